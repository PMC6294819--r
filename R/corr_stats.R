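# Clinical correlation analysis: plain Pearson among clinical variables and
# the three-family partial-correlation screen of acoustic features against
# FOG-Q items, controlling for clinical covariates.

#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation on pairwise-complete observations, two-sided p
#' from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3 complete pairs).
#' @return List with `estimate`, `p.value`, `n`, `method`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  structure(list(estimate = r, p.value = 2 * pt(-abs(tstat), n - 2),
                 n = n, method = "pearson", covariates = character(0)),
            class = "hd_corr")
}

# Null variance of tau-b with tie corrections (the var(S) expansion used by
# classical Kendall tests, divided by the tau-b normaliser squared).
tau_b_var <- function(x, y) {
  n <- length(x)
  t_x <- as.numeric(table(x)); t_y <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t_x * (t_x - 1) * (2 * t_x + 5))
  vu <- sum(t_y * (t_y - 1) * (2 * t_y + 5))
  v1 <- sum(t_x * (t_x - 1)) * sum(t_y * (t_y - 1)) / (2 * n * (n - 1))
  v2 <- sum(t_x * (t_x - 1) * (t_x - 2)) * sum(t_y * (t_y - 1) * (t_y - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  n0 <- n * (n - 1) / 2
  n1 <- sum(t_x * (t_x - 1)) / 2
  n2 <- sum(t_y * (t_y - 1)) / 2
  varS / ((n0 - n1) * (n0 - n2))
}

#' Partial correlation (Pearson, Spearman or Kendall family)
#'
#' Pearson: correlate the residuals of `x` and `y` after linear regression on
#' the covariates (algebraically identical to the inverse-correlation-matrix
#' formula); two-sided p from t with `n - 2 - k` degrees of freedom.
#' Spearman: the same after rank-transforming every variable (average ranks
#' on ties). Kendall: tau-b among all variables, then the first-order
#' partial-correlation recursion applied iteratively to remove each
#' covariate; p from the normal approximation to tau using the tie-corrected
#' null variance of tau-b.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates (or `NULL`).
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return List with `estimate`, `p.value`, `n`, `method`, `covariates`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_corr(x, y, cbind(z = z), "pearson")$estimate
#' @export
partial_corr <- function(x, y, covariates = NULL,
                         method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  k <- if (is.null(Z)) 0L else ncol(Z)
  ok <- is.finite(x) & is.finite(y)
  if (k) ok <- ok & apply(is.finite(Z), 1, all)
  x <- x[ok]; y <- y[ok]; if (k) Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2) stop("need n > k + 2 complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  if (k && qr(cbind(1, Z))$rank < k + 1)
    stop("rank-deficient covariates", call. = FALSE)

  if (method %in% c("pearson", "spearman")) {
    if (method == "spearman") {
      x <- rank(x); y <- rank(y)
      if (k) Z <- apply(Z, 2, rank)
    }
    if (k) {
      X <- cbind(1, Z)
      rx <- x - X %*% qr.coef(qr(X), x)
      ry <- y - X %*% qr.coef(qr(X), y)
    } else { rx <- x - mean(x); ry <- y - mean(y) }
    r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    df <- n - 2 - k
    tstat <- r * sqrt(df / max(1e-300, 1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  } else {
    vars <- cbind(x = x, y = y, Z)
    R <- cor(vars, method = "kendall")
    # iteratively remove covariate m from all remaining pairs
    while (ncol(R) > 2) {
      m <- ncol(R)
      keep <- seq_len(m - 1)
      Rn <- R[keep, keep, drop = FALSE]
      for (i in keep) for (j in keep) if (i != j) {
        den <- sqrt((1 - R[i, m]^2) * (1 - R[j, m]^2))
        Rn[i, j] <- if (den > 0) (R[i, j] - R[i, m] * R[j, m]) / den else NA_real_
      }
      R <- Rn
    }
    r <- R[1, 2]
    # tie-corrected null variance of tau-b; the recursion already shrinks
    # the statistic, so no additional covariate discount is applied
    v <- tau_b_var(x, y)
    p <- 2 * pnorm(-abs(r) / sqrt(v))
  }
  structure(list(estimate = unname(r), p.value = unname(p), n = n,
                 method = method,
                 covariates = if (k) colnames(Z) %||% paste0("z", 1:k)
                              else character(0)),
            class = "hd_corr")
}

#' @export
print.hd_corr <- function(x, ...) {
  cat(sprintf("%s%s correlation: r = %.4f, p = %.4g, n = %d\n",
              if (length(x$covariates)) "partial " else "",
              x$method, x$estimate, x$p.value, x$n))
  if (length(x$covariates))
    cat("  controlling for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Screen acoustic features against FOG-Q items by partial correlation
#'
#' Every (feature, item) pair is tested with Pearson, Spearman and Kendall
#' partial correlations controlling for the configured covariates. A pair
#' passes when all three p-values fall below `alpha` (the all-three rule,
#' which can only be as liberal as the strictest single method). The full
#' table is retained, not only the passing rows; Benjamini-Hochberg adjusted
#' p-values are reported per method for transparency, but the pass rule is
#' the unadjusted `alpha`.
#'
#' @param features a wide `feature_table` (see [feature_table]); session-1
#'   rows are used when a `session` column is present.
#' @param cohort cohort data.frame with `subject_id`, `session`, the FOG-Q
#'   items `Q3`..`Q6`, `total`, and the covariate columns.
#' @param alpha significance level (default 0.05).
#' @param covariates covariate column names (default age, gender, LED,
#'   UPDRS_III, BDI, ACE_R).
#' @param items FOG-Q columns to screen against.
#' @param config an [hd_config] supplying defaults.
#' @return A `fog_screen` object: data.frame with per-method `r_*`/`p_*`
#'   columns, adjusted `padj_*` columns, `n` and `pass`.
#' @export
fog_screen <- function(features, cohort, alpha = NULL, covariates = NULL,
                       items = c("Q3", "Q4", "Q5", "Q6", "total"),
                       config = hd_config()) {
  alpha <- alpha %||% config$alpha
  covariates <- covariates %||% config$covariates
  if ("session" %in% names(features))
    features <- features[features$session == 1, , drop = FALSE]
  ses1 <- cohort[cohort$session == 1, , drop = FALSE]
  merged <- merge(features, ses1, by = "subject_id",
                  suffixes = c("", ".cohort"))
  dropped <- setdiff(features$subject_id, merged$subject_id)
  k <- length(covariates)
  if (nrow(merged) <= k + 3)
    stop("too few joinable subjects (", nrow(merged), "); dropped: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  miss <- setdiff(c(covariates, items), names(merged))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)

  fcols <- setdiff(names(features), c("subject_id", "session"))
  Z <- merged[covariates]
  out <- list(); idx <- 0L
  for (fc in fcols) {
    for (it in items) {
      idx <- idx + 1L
      res <- lapply(c("pearson", "spearman", "kendall"), function(m)
        tryCatch(partial_corr(merged[[fc]], merged[[it]], Z, m),
                 error = function(e) list(estimate = NA_real_,
                                          p.value = NA_real_, n = NA_integer_)))
      out[[idx]] <- data.frame(
        feature = fc,
        measure = sub("_TSK.*$", "", fc),
        task = sub("^.*_(TSK[0-9]+)$", "\\1", fc),
        item = it,
        r_pearson = res[[1]]$estimate, p_pearson = res[[1]]$p.value,
        r_spearman = res[[2]]$estimate, p_spearman = res[[2]]$p.value,
        r_kendall = res[[3]]$estimate, p_kendall = res[[3]]$p.value,
        n = res[[1]]$n, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  for (m in c("pearson", "spearman", "kendall"))
    tab[[paste0("padj_", m)]] <- stats::p.adjust(tab[[paste0("p_", m)]], "BH")
  tab$pass <- !is.na(tab$p_pearson) & tab$p_pearson < alpha &
    tab$p_spearman < alpha & tab$p_kendall < alpha
  structure(tab, class = c("fog_screen", "data.frame"),
            alpha = alpha, covariates = covariates)
}

#' @export
print.fog_screen <- function(x, ...) {
  cat(sprintf("<fog_screen> %d feature x item tests, alpha = %g, %d pass all three methods\n",
              nrow(x), attr(x, "alpha"), sum(x$pass, na.rm = TRUE)))
  cat("  controlling for:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  if (any(x$pass, na.rm = TRUE)) {
    sig <- x[which(x$pass), c("feature", "item", "r_pearson", "p_pearson",
                              "r_spearman", "p_spearman", "r_kendall", "p_kendall")]
    print.data.frame(sig, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.fog_screen <- function(object, ...) {
  cat(sprintf("Screen of %d features x %d items (n per test: %s)\n",
              length(unique(object$feature)), length(unique(object$item)),
              paste(range(object$n, na.rm = TRUE), collapse = "-")))
  for (m in c("pearson", "spearman", "kendall")) {
    p <- object[[paste0("p_", m)]]
    cat(sprintf("  %-9s flagged %d / %d at alpha = %g\n", m,
                sum(p < attr(object, "alpha"), na.rm = TRUE), sum(!is.na(p)),
                attr(object, "alpha")))
  }
  cat(sprintf("  all-three pass: %d\n", sum(object$pass, na.rm = TRUE)))
  invisible(object)
}

#' Write a screen report as delimited text
#'
#' @param screen a [fog_screen] result.
#' @param path output path (tab-delimited).
#' @param provenance optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(as.data.frame(screen), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from delimited text
#'
#' Header contract: `subject_id`, `session` (1 or 2), demographics `age`,
#' `gender` (0/1), clinical scores `PD_dur`, `UPDRS_III`, `LED`, `NMSS`,
#' `RBDSQ`, `MMSE`, `ACE_R`, `BDI`, and FOG-Q columns `Q3`, `Q4`, `Q5`,
#' `Q6`, `total`.
#'
#' @param path tab- or comma-delimited file (delimiter sniffed from the
#'   header line). Lines starting with `#` are ignored.
#' @return A data.frame.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "Q3", "Q4", "Q5", "Q6", "total")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- with(df, total != Q3 + Q4 + Q5 + Q6)
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE), " rows where total != Q3+Q4+Q5+Q6")
  df
}
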