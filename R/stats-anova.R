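#' Repeated-measures ANOVA with partial eta squared and
#' Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for one or two factors on one observation
#' per subject and cell (aggregate to cell means first). Each effect is
#' tested against its own subject-by-effect error stratum, as in the
#' univariate mixed-model approach. Partial eta squared is
#' SS_effect / (SS_effect + SS_error). For effects with more than one
#' numerator degree of freedom, the Greenhouse-Geisser epsilon and the
#' corrected p-value are reported alongside Mauchly's sphericity test;
#' the `applied` column records whether the correction is needed under
#' the `mauchly_alpha` trigger.
#'
#' @param data Long tibble, one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param id Name of the subject identifier column.
#' @param mauchly_alpha Significance level of Mauchly's test below which
#'   the Greenhouse-Geisser corrected p is the one to report.
#' @return Object of class `kf_anova`; its `table` element is a tibble
#'   with `effect`, `df1`, `df2`, `ss`, `ss_error`, `statistic`, `p`,
#'   `pes`, `gg_epsilon`, `p_gg`, `mauchly_p`, `applied`.
#' @examples
#' d <- tidyr::crossing(id = 1:8, a = c("x", "y"))
#' d$y <- stats::rnorm(nrow(d))
#' rm_anova(d, "y", "a")
#' @export
rm_anova <- function(data, dv, within, id = "participant_id",
                     mauchly_alpha = 0.05) {
  stopifnot(length(within) %in% 1:2)
  for (col in c(dv, within, id)) {
    if (!col %in% names(data)) rlang::abort(sprintf("column `%s` not found.", col))
  }
  data <- dplyr::ungroup(data)
  for (w in within) data[[w]] <- factor(data[[w]])
  levs <- lapply(within, function(w) levels(data[[w]]))
  cells <- do.call(tidyr::crossing, stats::setNames(levs, within))
  wide <- data |>
    dplyr::select(dplyr::all_of(c(id, within, dv))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(within),
                       values_from = dplyr::all_of(dv),
                       names_sep = "\r")
  cell_names <- apply(cells, 1, paste, collapse = "\r")
  if (!all(cell_names %in% names(wide)) ||
      anyNA(wide[, cell_names])) {
    rlang::abort("design has missing subject x cell combinations.")
  }
  Y <- as.matrix(wide[, cell_names])
  n <- nrow(Y)
  if (n < 2) rlang::abort("need at least two subjects.")

  ortho <- function(k) {
    # orthonormal contrasts spanning deviations from the mean
    qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
  }
  unit <- function(k) matrix(1 / sqrt(k), k, 1)

  k1 <- length(levs[[1]])
  effs <- list()
  if (length(within) == 1) {
    effs[[within[1]]] <- ortho(k1)
  } else {
    k2 <- length(levs[[2]])
    effs[[within[1]]] <- kronecker(ortho(k1), unit(k2))
    effs[[within[2]]] <- kronecker(unit(k1), ortho(k2))
    effs[[paste(within, collapse = ":")]] <- kronecker(ortho(k1), ortho(k2))
  }

  rows <- lapply(names(effs), function(nm) {
    C <- effs[[nm]]
    S <- Y %*% C                       # subject scores on the contrasts
    k <- ncol(S)
    mbar <- colMeans(S)
    ss_eff <- n * sum(mbar^2)
    resid <- sweep(S, 2, mbar)
    ss_err <- sum(resid^2)
    df1 <- k
    df2 <- k * (n - 1)
    tol <- 1e-18 * max(1, sum(Y^2))
    if (ss_eff + ss_err <= tol) {
      # contrast scores are numerically zero (identical cells)
      F_ <- 0; p <- 1
    } else if (ss_err <= tol) {
      F_ <- Inf; p <- 0
    } else {
      F_ <- (ss_eff / df1) / (ss_err / df2)
      p <- stats::pf(F_, df1, df2, lower.tail = FALSE)
    }
    eps <- NA_real_; p_gg <- NA_real_; mau <- NA_real_; applied <- FALSE
    if (k > 1) {
      V <- crossprod(resid) / (n - 1)  # covariance of contrast scores
      lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
      eps <- sum(lam)^2 / (k * sum(lam^2))
      p_gg <- stats::pf(F_, eps * df1, eps * df2, lower.tail = FALSE)
      if (n - 1 >= k) {
        W <- det(V) / (sum(diag(V)) / k)^k
        if (is.finite(W) && W > 0) {
          chi <- -(n - 1 - (2 * k^2 + k + 2) / (6 * k)) * log(W)
          mau <- stats::pchisq(chi, k * (k + 1) / 2 - 1, lower.tail = FALSE)
          applied <- mau < mauchly_alpha
        }
      }
    }
    tibble::tibble(effect = nm, df1 = df1, df2 = df2, ss = ss_eff,
                   ss_error = ss_err, statistic = F_, p = p,
                   pes = ss_eff / (ss_eff + ss_err),
                   gg_epsilon = eps, p_gg = p_gg, mauchly_p = mau,
                   applied = applied)
  })
  structure(list(table = dplyr::bind_rows(rows), n = n, dv = dv,
                 within = within), class = "kf_anova")
}

#' @export
print.kf_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA on %s (n = %d)\n", x$dv, x$n))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    gg <- if (!is.na(r$gg_epsilon))
      sprintf(" (eps = %.2f, p_GG = %.4g)", r$gg_epsilon, r$p_gg) else ""
    cat(sprintf("  %s: F(%g, %g) = %.2f, p = %.4g, pes = %.2f%s\n",
                r$effect, r$df1, r$df2, r$statistic, r$p, r$pes, gg))
  }
  invisible(x)
}
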