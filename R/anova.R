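#' Sequential and adjusted ANOVA for a fitted response surface
#'
#' Produces the standard Minitab-style decomposition for a full quadratic
#' response-surface fit: sequential (Type I) sums of squares in a stated term
#' order, adjusted (Type III) sums of squares from drop-term refits, grouped
#' Linear / Square / Interaction rows, and the split of the residual into
#' lack-of-fit and pure error from replicated runs. F ratios divide each
#' adjusted mean square by the residual mean square (lack-of-fit is tested
#' against pure error) and p-values come from the upper tail of the F
#' distribution.
#'
#' The decomposition is computed on the w/w fraction response scale by
#' default, the scale on which replicate scatter in selectivity data has
#' interpretable magnitude; F ratios, p-values and R2 are identical on either
#' scale.
#'
#' @param fit An `sfe_surface` from [fit_surface()].
#' @param order Character permutation of the factor names fixing the
#'   sequential order; squares follow the same permutation and interactions
#'   are taken in lexicographic pair order of it. Default: declared factor
#'   order. Sequential SS depend on this order; adjusted SS and F do not.
#' @param scale Response scale on which to compute the table.
#' @return A tibble of class `sfe_anova` with columns `source`, `df`,
#'   `seq_ss`, `adj_ss`, `adj_ms`, `statistic`, `p.value`.
#' @examples
#' fit <- fit_surface(sfe_fixture("table3"), "selectivity", scale = "fraction")
#' surface_anova(fit, order = c("T", "P", "G"))
#' @export
surface_anova <- function(fit, order = NULL,
                          scale = c("fraction", "percent", "as_fit")) {
  scale <- match.arg(scale)
  if (!inherits(fit, "sfe_surface")) abort("`fit` must be an sfe_surface")
  if (scale != "as_fit" && fit$response_scale != scale) {
    fit <- rescale_surface(fit, scale)
  }
  fac <- fit$factors$name
  if (is.null(order)) order <- fac
  if (!setequal(order, fac) || length(order) != length(fac)) {
    abort(paste0("`order` must be a permutation of: ", paste(fac, collapse = ", ")))
  }
  data <- fit$data
  response <- fit$response
  n <- nrow(data)
  k <- length(fac)

  lin <- order
  sq <- paste0("I(", order, "^2)")
  pairs <- utils::combn(order, 2)
  inter <- paste0(pairs[1, ], ":", pairs[2, ])
  terms_ordered <- c(lin, sq, inter)

  fml_full <- stats::reformulate(terms_ordered, response = as.name(response))
  full <- lm(fml_full, data = data)
  sse <- sum(resid(full)^2)
  df_res <- full$df.residual
  mse <- sse / df_res
  y <- data[[response]]
  sst <- sum((y - mean(y))^2)

  seq_tab <- anova(full)
  seq_ss <- setNames(seq_tab[["Sum Sq"]], rownames(seq_tab))

  drop_ss <- function(drop_terms) {
    keep <- setdiff(terms_ordered, drop_terms)
    fml <- stats::reformulate(keep, response = as.name(response))
    sum(resid(lm(fml, data = data))^2) - sse
  }
  adj_single <- vapply(terms_ordered, function(tm) drop_ss(tm), numeric(1))
  adj_lin <- drop_ss(lin)
  adj_sq <- drop_ss(sq)
  adj_int <- drop_ss(inter)

  # replicate-based residual split
  groups <- replicate_groups(data)
  ss_pe <- sum(vapply(groups, function(idx) {
    v <- y[idx]
    sum((v - mean(v))^2)
  }, numeric(1)))
  df_pe <- pure_error_df(data)
  has_pe <- df_pe > 0L
  warnings <- character(0)
  if (!has_pe) {
    warnings <- "no replicated runs: lack-of-fit and pure-error rows omitted"
    warn(warnings)
  }

  row <- function(source, df, seq, adj, against_ms = mse, against_df = df_res,
                  test = TRUE) {
    ms <- if (df > 0) adj / df else NA_real_
    f <- if (test && !is.na(ms) && !is.na(against_ms) && against_ms > 0 && ms > 0) {
      ms / against_ms
    } else if (test && !is.na(ms) && ms == 0) NA_real_ else NA_real_
    p <- if (!is.na(f)) pf(f, df, against_df, lower.tail = FALSE) else NA_real_
    tibble::tibble(source = source, df = as.integer(df), seq_ss = seq,
                   adj_ss = adj, adj_ms = ms, statistic = f, p.value = p)
  }

  ss_model <- sst - sse
  df_model <- n - 1L - df_res
  rows <- list(
    row("Regression", df_model, ss_model, ss_model),
    row("Linear", k, sum(seq_ss[lin]), adj_lin)
  )
  for (tm in lin) rows <- c(rows, list(row(tm, 1L, seq_ss[[tm]], adj_single[[tm]])))
  rows <- c(rows, list(row("Square", k, sum(seq_ss[sq]), adj_sq)))
  for (i in seq_along(sq)) {
    rows <- c(rows, list(row(paste0(order[i], "*", order[i]), 1L,
                             seq_ss[[sq[i]]], adj_single[[sq[i]]])))
  }
  rows <- c(rows, list(row("Interaction", length(inter), sum(seq_ss[inter]), adj_int)))
  for (i in seq_along(inter)) {
    rows <- c(rows, list(row(paste0(pairs[1, i], "*", pairs[2, i]), 1L,
                             seq_ss[[inter[i]]], adj_single[[inter[i]]])))
  }
  rows <- c(rows, list(row("Residual error", df_res, sse, sse, test = FALSE)))
  if (has_pe) {
    ss_lof <- sse - ss_pe
    df_lof <- df_res - df_pe
    ms_pe <- ss_pe / df_pe
    rows <- c(rows, list(
      row("Lack-of-fit", df_lof, ss_lof, ss_lof,
          against_ms = ms_pe, against_df = df_pe),
      row("Pure error", df_pe, ss_pe, ss_pe, test = FALSE)
    ))
  }
  rows <- c(rows, list(
    tibble::tibble(source = "Total", df = n - 1L, seq_ss = sst,
                   adj_ss = NA_real_, adj_ms = NA_real_,
                   statistic = NA_real_, p.value = NA_real_)
  ))
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("sfe_anova", class(out)),
    response = response,
    scale = fit$response_scale,
    order = order,
    r_squared = ss_model / sst,
    warnings = warnings
  )
}

#' @export
print.sfe_anova <- function(x, ...) {
  cat("Analysis of variance for `", attr(x, "response"), "` (",
      attr(x, "scale"), " scale; sequential order: ",
      paste(attr(x, "order"), collapse = ", "), ")\n\n", sep = "")
  cat(format_anova(x), sep = "\n")
  cat("\nR-squared:", format(attr(x, "r_squared"), digits = 6), "\n")
  invisible(x)
}

format_anova <- function(x) {
  fmt <- function(v, digits = 6) ifelse(is.na(v), "", formatC(v, digits = digits, format = "g"))
  body <- data.frame(
    Source = x$source, DF = x$df,
    SeqSS = fmt(x$seq_ss), AdjSS = fmt(x$adj_ss), AdjMS = fmt(x$adj_ms),
    F = fmt(x$statistic, 4), p = fmt(x$p.value, 3)
  )
  utils::capture.output(print(body, row.names = FALSE))
}

#' Write an ANOVA table to CSV
#'
#' Columns mirror the conventional printed layout: Source, DF, SeqSS, AdjSS,
#' AdjMS, F, p.
#'
#' @param x An `sfe_anova`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(x, path) {
  out <- tibble::tibble(
    Source = x$source, DF = x$df, SeqSS = x$seq_ss, AdjSS = x$adj_ss,
    AdjMS = x$adj_ms, F = x$statistic, p = x$p.value
  )
  readr::write_csv(out, path)
  invisible(path)
}
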