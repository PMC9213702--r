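#' Associate reaction abundances with plasma metabolite levels
#'
#' For every (reaction, metabolite) pair, fits the fixed-effects linear
#' model `metabolite ~ log-transformed reaction abundance + covariates`
#' by least squares and reports the coefficient and p-value of the
#' abundance term, with Benjamini-Hochberg adjustment across all pairs.
#' Reaction abundances are log-transformed with a pseudo-count of half the
#' smallest nonzero abundance, countering their heavy right skew. The fit
#' is computed by residualizing both sides on the covariates
#' (Frisch-Waugh-Lovell), which is algebraically identical to the full OLS
#' fit but vectorizes over all pairs.
#'
#' @param ra reaction-abundance table (tibble with `sample_id`, or matrix).
#' @param met plasma metabolite table (tibble with `sample_id`, or matrix);
#'   samples are matched by id with `ra`.
#' @param meta sample metadata holding the covariate columns.
#' @param covariates character vector of metadata columns to adjust for
#'   (default `c("age", "sex", "bmi")`); numeric columns are median-imputed,
#'   `sex` is coded M = 1 / F = 0 with unknowns imputed to the median.
#' @param fdr_threshold threshold used for the `significant` flag
#'   (default 0.01).
#' @return a tibble `reaction_id`, `metabolite_id`, `coefficient`,
#'   `p_value`, `fdr`, `sign`, `significant`; pairs with a constant
#'   predictor or response are skipped (reported via a message).
#' @export
fit_associations <- function(ra, met, meta,
                             covariates = c("age", "sex", "bmi"),
                             fdr_threshold = 0.01) {
  Z <- if (is.matrix(ra)) ra else table_to_matrix(ra)
  Y <- if (is.matrix(met)) met else table_to_matrix(met)
  samples <- intersect(rownames(Z), rownames(Y))
  samples <- intersect(samples, meta$sample_id)
  if (length(samples) < 10L)
    stop("need at least 10 overlapping samples, have ", length(samples))
  Z <- Z[samples, , drop = FALSE]
  Y <- Y[samples, , drop = FALSE]
  meta <- meta[match(samples, meta$sample_id), ]

  X <- cbind(`(Intercept)` = rep(1, length(samples)),
             covariate_matrix(meta, covariates))
  # log transform with half-minimum pseudo-count
  nonzero <- Z[Z > 0]
  eps <- if (length(nonzero)) min(nonzero) / 2 else 1e-9
  Zt <- log(Z + eps)

  keep_z <- apply(Zt, 2, function(v) stats::sd(v) > 0)
  keep_y <- apply(Y, 2, function(v) stats::sd(v) > 0)
  if (any(!keep_z))
    message("skipping constant reactions: ", sum(!keep_z))
  if (any(!keep_y))
    message("skipping constant metabolites: ", sum(!keep_y))
  Zt <- Zt[, keep_z, drop = FALSE]
  Y <- Y[, keep_y, drop = FALSE]
  if (ncol(Zt) == 0L || ncol(Y) == 0L)
    stop("no non-constant reaction/metabolite columns left")

  qrX <- qr(X)
  Rz <- Zt - qr.fitted(qrX, Zt)
  Ry <- Y - qr.fitted(qrX, Y)
  denom <- colSums(Rz^2)
  if (any(denom <= 0)) {
    ok <- denom > 0
    message("skipping reactions collinear with covariates: ", sum(!ok))
    Rz <- Rz[, ok, drop = FALSE]
    Zt <- Zt[, ok, drop = FALSE]
    denom <- denom[ok]
  }
  yss <- colSums(Ry^2)
  C <- crossprod(Rz, Ry)                      # reactions x metabolites
  coef <- C / denom
  df <- length(samples) - qrX$rank - 1L
  if (df < 1L) stop("not enough residual degrees of freedom")
  sse <- pmax(sweep(-C^2 / denom, 2, yss, `+`), 0)
  se <- sqrt((sse / df) / denom)
  tstat <- coef / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.nan(tstat)] <- 1 # 0/0: no residual variance and no effect

  out <- tibble::tibble(
    reaction_id = rep(colnames(Zt), times = ncol(Y)),
    metabolite_id = rep(colnames(Y), each = ncol(Zt)),
    coefficient = as.vector(coef),
    p_value = as.vector(p))
  out$fdr <- benjamini_hochberg(out$p_value)
  out$sign <- ifelse(out$coefficient >= 0, "positive", "negative")
  out$significant <- out$fdr < fdr_threshold
  dplyr::arrange(out, .data$fdr, .data$p_value)
}

covariate_matrix <- function(meta, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(meta)) stop("metadata lacks covariate '", cv, "'")
    v <- meta[[cv]]
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      num <- dplyr::case_when(v %in% c("M", "male") ~ 1,
                              v %in% c("F", "female") ~ 0,
                              TRUE ~ NA_real_)
    } else num <- as.numeric(v)
    if (anyNA(num)) num[is.na(num)] <- stats::median(num, na.rm = TRUE)
    num
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Compare reaction abundances between BMI strata
#'
#' Splits samples at a BMI cut (default 30, the obesity boundary) and runs
#' a two-tailed Wilcoxon rank-sum test per reaction between the two
#' strata. Raw p-values are compared against `alpha` without multiplicity
#' adjustment, matching the exploratory use of this comparison. Samples
#' with BMI exactly at the cut are placed in the lower stratum (and
#' counted in the output so the choice is visible).
#'
#' @param ra reaction-abundance table.
#' @param meta metadata with `sample_id` and `bmi`.
#' @param reactions optional reaction ids to restrict to.
#' @param bmi_cut BMI boundary (default 30 kg/m2).
#' @param alpha significance level on the raw p (default 0.05).
#' @return tibble `reaction_id`, `p_value`, `significant`, `direction`
#'   (`"higher in obese"` / `"lower in obese"`), `mean_high`, `mean_low`,
#'   `n_high`, `n_low`, `n_at_cut`.
#' @export
bmi_stratified_test <- function(ra, meta, reactions = NULL, bmi_cut = 30,
                                alpha = 0.05) {
  m <- if (is.matrix(ra)) ra else table_to_matrix(ra)
  stopifnot(all(c("sample_id", "bmi") %in% names(meta)))
  meta <- meta[meta$sample_id %in% rownames(m) & !is.na(meta$bmi), ]
  high <- meta$sample_id[meta$bmi > bmi_cut]
  low <- meta$sample_id[meta$bmi <= bmi_cut]
  n_at_cut <- sum(meta$bmi == bmi_cut)
  if (length(high) < 2L || length(low) < 2L)
    stop("each BMI stratum needs at least 2 samples")
  if (!is.null(reactions)) m <- m[, intersect(reactions, colnames(m)), drop = FALSE]
  if (ncol(m) == 0L) stop("no requested reactions found in the table")
  mh <- m[high, , drop = FALSE]
  ml <- m[low, , drop = FALSE]
  p <- vapply(seq_len(ncol(m)), function(j) wilcoxon_two_sided(mh[, j], ml[, j]), 0)
  mean_high <- colMeans(mh); mean_low <- colMeans(ml)
  tibble::tibble(
    reaction_id = colnames(m),
    p_value = p,
    significant = p < alpha,
    direction = unname(ifelse(mean_high > mean_low,
                              "higher in obese", "lower in obese")),
    mean_high = unname(mean_high),
    mean_low = unname(mean_low),
    n_high = length(high), n_low = length(low), n_at_cut = n_at_cut)
}
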