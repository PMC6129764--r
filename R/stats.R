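# Voxel-wise group statistics, image-based meta-analysis combiners and
# multiple-comparison corrections.

#' Voxel-wise t-tests with covariates
#'
#' Per voxel, a least-squares fit of the map value on
#' `[intercept, group, covariates]`; the t statistic is on the group
#' coefficient with `df = n - p` and a two-sided p by default.
#' `contrast = "one"` tests the intercept of `[intercept, covariates]`
#' against zero; `"paired"` is the one-sample test on within-pair
#' differences (matched ordering of the two groups).
#'
#' @param maps Subjects x voxels matrix, or list of single-frame
#'   [volume4d()] maps (with `mask`).
#' @param groups Two-level factor/vector of group labels (two-sample and
#'   paired designs).
#' @param covariates Optional numeric matrix of per-subject covariates.
#' @param contrast `"two"`, `"one"` or `"paired"`.
#' @param mask Optional [brain_mask()] when `maps` are volumes; output maps
#'   are returned on this grid.
#' @param two_sided Two-sided p-values (default TRUE).
#' @return A `stat_map`: `stat`, `df`, `p` (vectors, or [volume4d()] maps
#'   when `mask` is given).
#' @export
glm_ttest <- function(maps, groups = NULL, covariates = NULL,
                      contrast = c("two", "one", "paired"), mask = NULL,
                      two_sided = TRUE) {
  contrast <- match.arg(contrast)
  Y <- maps_to_matrix(maps, mask)
  n <- nrow(Y)
  if (contrast == "paired") {
    g <- as.factor(groups)
    if (nlevels(g) != 2) stop("paired design needs two groups")
    a <- which(g == levels(g)[1])
    b <- which(g == levels(g)[2])
    if (length(a) != length(b))
      stop("paired design needs equal group sizes in matched order")
    Y <- Y[a, , drop = FALSE] - Y[b, , drop = FALSE]
    n <- nrow(Y)
    X <- cbind(intercept = rep(1, n))
    test_col <- 1L
  } else if (contrast == "one") {
    X <- cbind(intercept = rep(1, n))
    test_col <- 1L
  } else {
    g <- as.factor(groups)
    if (nlevels(g) != 2) stop("two-sample design needs two groups")
    X <- cbind(intercept = rep(1, n),
               group = as.numeric(g == levels(g)[2]))
    test_col <- 2L
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (contrast == "paired")
      stop("covariates are not supported in the paired design")
    colnames(covariates) <- colnames(covariates) %||%
      paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  p_cols <- ncol(X)
  if (n <= p_cols) stop("need more subjects than design columns")
  qrX <- qr(X)
  if (qrX$rank < p_cols) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[setdiff(seq_len(p_cols), piv)], collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- n - p_cols
  sigma2 <- colSums(res^2) / df
  # voxels whose residuals vanish to rounding noise carry no evidence
  zero_var <- sigma2 <= .Machine$double.eps * (colSums(Y^2) / df + 1)
  xtxinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtxinv[test_col, test_col])
  tstat <- ifelse(se > 0 & !zero_var, beta[test_col, ] / se, 0)
  p <- if (two_sided) 2 * stats::pt(-abs(tstat), df)
       else stats::pt(tstat, df, lower.tail = FALSE)
  stat_map(tstat, df, p, mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

maps_to_matrix <- function(maps, mask) {
  if (is.matrix(maps)) return(maps)
  if (!is.list(maps)) stop("'maps' must be a matrix or a list of volumes")
  if (is.null(mask)) stop("volume input requires a mask")
  do.call(rbind, lapply(maps, function(v)
    volume_to_matrix(v, mask)$values[1, ]))
}

#' Construct a statistic map
#'
#' @param stat Statistic values (vector, or map when `mask` given).
#' @param df Degrees of freedom (scalar).
#' @param p P-values matching `stat`.
#' @param mask Optional [brain_mask()]; converts vectors to map volumes.
#' @return A `stat_map` object.
#' @export
stat_map <- function(stat, df, p, mask = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- list(stat = stat, df = df, p = p, mask = mask)
  if (!is.null(mask)) {
    idx <- which(mask$data)
    tovol <- function(v)
      matrix_to_volume(ts_matrix(matrix(v, nrow = 1), idx, tr = 1,
                                 dim(mask$data)), mask)
    out$stat <- tovol(stat)
    out$p <- tovol(p)
  }
  structure(out, class = "stat_map")
}

stat_values <- function(sm) {
  if (inherits(sm$stat, "volume4d"))
    volume_to_matrix(sm$stat, sm$mask)$values[1, ]
  else sm$stat
}

p_values <- function(sm) {
  if (inherits(sm$p, "volume4d"))
    volume_to_matrix(sm$p, sm$mask)$values[1, ]
  else sm$p
}

#' Bundle a study for image-based meta-analysis
#'
#' @param z Per-voxel z values (for `stouffer`; signed).
#' @param p Per-voxel p-values (for `fisher`, `worsley_friston`,
#'   `nichols`); derived from `z` if missing.
#' @param effect Per-voxel effect estimates (for `fixed` / `mixed`).
#' @param variance Per-voxel effect variances (for `fixed` / `mixed`).
#' @param n Sample size (metadata).
#' @return An `ibma_study` object.
#' @export
ibma_study <- function(z = NULL, p = NULL, effect = NULL, variance = NULL,
                       n = NULL) {
  structure(list(z = z, p = p, effect = effect, variance = variance, n = n),
            class = "ibma_study")
}

#' Image-based meta-analysis combiners
#'
#' Per voxel across k studies:
#' \describe{
#'   \item{stouffer}{z_c = sum(z_i) / sqrt(k); p from the normal tail.}
#'   \item{fisher}{X = -2 sum(log p_i), chi-squared with 2k df.}
#'   \item{fixed}{inverse-variance weighted effect, w_i = 1 / v_i;
#'     z = sum(w_i theta_i) / sqrt(sum(w_i)).}
#'   \item{mixed}{as fixed with v_i + tau^2, tau^2 the DerSimonian-Laird
#'     moment estimate floored at 0.}
#'   \item{worsley_friston}{p_c = (max p_i)^k (conjunction).}
#'   \item{nichols}{p_c = max p_i.}
#' }
#'
#' @param studies List of [ibma_study()] objects on a common grid.
#' @param method Combiner name.
#' @return A list with per-voxel `stat` (z or X where defined), `p`, `df`
#'   where applicable, and for effect methods `effect` and `se`.
#' @export
ibma_combine <- function(studies,
                         method = c("stouffer", "fisher", "fixed", "mixed",
                                    "worsley_friston", "nichols")) {
  method <- match.arg(method)
  if (length(studies) < 2) stop("meta-analysis requires at least 2 studies")
  k <- length(studies)
  get_p <- function(s) {
    if (!is.null(s$p)) return(clip_p(s$p))
    if (!is.null(s$z)) return(2 * stats::pnorm(-abs(s$z)))
    stop("study lacks p-values (and no z to derive them from)")
  }
  if (method == "stouffer") {
    zs <- lapply(studies, function(s) {
      if (is.null(s$z)) stop("Stouffer's method requires z maps")
      s$z
    })
    zc <- Reduce(`+`, zs) / sqrt(k)
    list(stat = zc, p = 2 * stats::pnorm(-abs(zc)), method = method)
  } else if (method == "fisher") {
    ps <- lapply(studies, get_p)
    X <- -2 * Reduce(`+`, lapply(ps, log))
    list(stat = X, df = 2 * k,
         p = stats::pchisq(X, df = 2 * k, lower.tail = FALSE),
         method = method)
  } else if (method %in% c("fixed", "mixed")) {
    eff <- lapply(studies, function(s) {
      if (is.null(s$effect) || is.null(s$variance))
        stop("effect-based methods require 'effect' and 'variance' maps")
      s
    })
    th <- do.call(rbind, lapply(eff, `[[`, "effect"))   # k x voxels
    v <- do.call(rbind, lapply(eff, `[[`, "variance"))
    tau2 <- 0
    if (method == "mixed") {
      w <- 1 / v
      thbar <- colSums(w * th) / colSums(w)
      Q <- colSums(w * sweep(th, 2, thbar)^2)
      c1 <- colSums(w) - colSums(w^2) / colSums(w)
      tau2 <- pmax(0, (Q - (k - 1)) / c1)
    }
    w <- 1 / sweep(v, 2, tau2, `+`)
    comb <- colSums(w * th) / colSums(w)
    se <- sqrt(1 / colSums(w))
    z <- colSums(w * th) / sqrt(colSums(w))
    list(stat = z, p = 2 * stats::pnorm(-abs(z)), effect = comb, se = se,
         tau2 = tau2, method = method)
  } else {
    ps <- do.call(rbind, lapply(studies, get_p))
    pmaxv <- apply(ps, 2, max)
    pc <- if (method == "worsley_friston") pmaxv^k else pmaxv
    list(stat = stats::qnorm(1 - pc), p = pc, method = method)
  }
}

clip_p <- function(p) {
  if (any(p <= 0, na.rm = TRUE)) {
    warning("p = 0 clipped to the smallest positive double")
    p[p <= 0] <- .Machine$double.xmin
  }
  p
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg (FDR, independent / positively dependent),
#' Benjamini-Yekutieli (FDR under arbitrary dependence, with the harmonic
#' constant c(m) = sum 1/j), and Bonferroni (FWER). Adjusted p-values use
#' the standard step-up recursions; a test is rejected when its adjusted p
#' is at most `q_or_alpha`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"bh"`, `"by"` or `"bonferroni"`.
#' @param q_or_alpha FDR level q or FWER level alpha (default 0.05).
#' @return List: `rejected` (logical), `adjusted` (numeric), `method`,
#'   `level`.
#' @export
correct_multiple <- function(p, method = c("bh", "by", "bonferroni"),
                             q_or_alpha = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0)
    return(list(rejected = logical(0), adjusted = numeric(0),
                method = method, level = q_or_alpha))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = c(bh = "BH", by = "BY",
                                       bonferroni = "bonferroni")[method])
  list(rejected = !is.na(adj) & adj <= q_or_alpha, adjusted = adj,
       method = method, level = q_or_alpha)
}
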