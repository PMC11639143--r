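#' Configuration of a 2-way admixture analysis
#'
#' Names the hybrid, the two putative donors and the set of auxiliary
#' populations (the "right"/"reference"/outgroup populations of the
#' f-statistics literature). Auxiliary populations are used only to define
#' projection directions: every unordered auxiliary pair (i, j) contributes
#' one axis of the random subspace in which the subspace estimators work.
#'
#' @param hybrid Label of the admixed population x.
#' @param donor_a,donor_b Labels of the two donors.
#' @param auxiliaries Character vector of k >= 2 auxiliary labels.
#' @return An `admixture_config2` object.
#' @export
admixture_config2 <- function(hybrid, donor_a, donor_b, auxiliaries) {
  labels <- c(hybrid, donor_a, donor_b, auxiliaries)
  stopifnot(is.character(labels) || is.factor(labels))
  if (anyDuplicated(labels)) {
    stop("hybrid, donors and auxiliaries must be disjoint")
  }
  if (length(auxiliaries) < 2L) {
    stop("at least k = 2 auxiliary populations are required")
  }
  structure(list(hybrid = hybrid, donor_a = donor_a, donor_b = donor_b,
                 auxiliaries = sort(as.character(auxiliaries))),
            class = "admixture_config2")
}

#' Full-phase-space estimate of the 2-way mixing coefficient
#'
#' Estimates alpha in the linear hybrid model `p_x = alpha p_a +
#' (1 - alpha) p_b` by a least-squares fit in the full allele-frequency
#' space: the through-origin slope of the point set
#' `{p_a - p_b, p_x - p_b}` over SNPs, which equals
#' `f3(a, x; b) / f2(a, b)`. Accurate when post-admixture drift is small;
#' the subspace estimator [alpha_jl()] is preferred otherwise.
#'
#' @param panel A [frequency_panel].
#' @param config An [admixture_config2].
#' @return List with `alpha`, `se`, `ci` (95% through-origin regression
#'   interval), `df`.
#' @export
alpha_full_space <- function(panel, config) {
  check_pops(panel, c(config$hybrid, config$donor_a, config$donor_b))
  pa <- pop_vector(panel, config$donor_a)
  pb <- pop_vector(panel, config$donor_b)
  px <- pop_vector(panel, config$hybrid)
  if (sum((pa - pb)^2) == 0) {
    stop("degenerate donors: f2(a, b) = 0", call. = FALSE)
  }
  fit <- origin_slope(pa - pb, px - pb)
  list(alpha = fit$estimate, se = fit$se, ci = fit$ci, df = fit$df)
}

#' Admixture angle phi in the full phase space
#'
#' The angle at the hybrid vertex x of the triangle (a, x, b) in allele
#' frequency space: `cos(phi) = f3(a, b; x) / sqrt(f2(a, x) f2(b, x))`.
#' An obtuse angle (90 < phi < 180 degrees, equivalently f3(a, b; x) < 0)
#' is the geometric admixture condition. The cosine is clamped to
#' \[-1, 1\] before `acos` to absorb floating-point overshoot.
#'
#' @inheritParams alpha_full_space
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_phi <- function(panel, config) {
  f2ax <- f2(panel, config$donor_a, config$hybrid)
  f2bx <- f2(panel, config$donor_b, config$hybrid)
  if (f2ax == 0 || f2bx == 0) {
    stop("undefined angle: hybrid coincides with a donor", call. = FALSE)
  }
  cosphi <- f3(panel, config$donor_a, config$donor_b, config$hybrid) /
    sqrt(f2ax * f2bx)
  deg(acos(clamp_cos(cosphi)))
}

#' Classical (full-space) admixture test
#'
#' Tests whether the hybrid lies geometrically between the donors:
#' passes iff `f3(a, b; x) < 0`, equivalently 90 < phi < 180 degrees.
#' Post-admixture drift erodes this signal, which is why the package also
#' reports the post-projection angle [angle_varphi()].
#'
#' @inheritParams alpha_full_space
#' @return List with `passed` (logical), `f3` and `phi_deg`.
#' @export
admixture_test_full <- function(panel, config) {
  f3v <- f3(panel, config$donor_a, config$donor_b, config$hybrid)
  # boundary case x == donor: f3 = 0 (not admixed) but phi is undefined
  phi <- tryCatch(angle_phi(panel, config), error = function(e) NA_real_)
  list(passed = f3v < 0, f3 = f3v, phi_deg = phi)
}

#' Build the auxiliary-pair regression point set
#'
#' Enumerates all unordered auxiliary pairs (i, j), i < j in lexicographic
#' label order, and computes for each the renormalized statistics
#' `f4'(a, b; i, j)` (predictor) and `f4'(x, b; i, j)` (response). In the
#' subspace spanned by the pair directions the hybrid model reads
#' `f4'(x, b; i, j) = alpha f4'(a, b; i, j)`, so the mixing coefficient is
#' the through-origin slope of this 2D point set. Pairs with
#' `f2(i, j) <= tol` define no direction and are excluded (count recorded
#' in attribute `n_excluded`).
#'
#' The weight column is the squared predictor: the through-origin slope is
#' the weighted average of single-pair f4-ratios with these weights, so
#' pairs with large shared drift with the donors dominate the estimate.
#'
#' @inheritParams alpha_full_space
#' @param tol Degenerate-pair threshold on f2(i, j).
#' @return An `f4_point_set`: data frame with columns `pair_i`, `pair_j`,
#'   `predictor`, `response`, `weight`, plus attributes `n_excluded`, `s`
#'   and `config`.
#' @export
build_f4_point_set <- function(panel, config, tol = 1e-12) {
  aux <- config$auxiliaries
  check_pops(panel, c(config$hybrid, config$donor_a, config$donor_b, aux))
  s <- n_snps(panel)
  A <- unclass(panel)[, aux, drop = FALSE]
  G <- crossprod(A)
  ssq <- diag(G)
  pa <- pop_vector(panel, config$donor_a)
  pb <- pop_vector(panel, config$donor_b)
  px <- pop_vector(panel, config$hybrid)
  vab <- as.vector(crossprod(A, pa - pb))
  vxb <- as.vector(crossprod(A, px - pb))
  k <- length(aux)
  ii <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  jj <- sequence((k - 1L):1L) + ii
  f2s <- ssq[ii] + ssq[jj] - 2 * G[cbind(ii, jj)]   # s * f2(i, j)
  usable <- f2s / s > tol
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    message(sprintf("build_f4_point_set: excluded %d degenerate auxiliary pair(s)",
                    n_excluded))
  }
  if (!any(usable)) stop("insufficient pairs: no usable auxiliary pair", call. = FALSE)
  ii <- ii[usable]; jj <- jj[usable]; f2s <- f2s[usable]
  pred <- s * (vab[ii] - vab[jj]) / f2s
  resp <- s * (vxb[ii] - vxb[jj]) / f2s
  out <- data.frame(pair_i = aux[ii], pair_j = aux[jj],
                    predictor = pred, response = resp,
                    weight = pred^2, stringsAsFactors = FALSE)
  structure(out, n_excluded = n_excluded, s = s, config = config,
            class = c("f4_point_set", "data.frame"))
}

#' Subspace (JL) estimate of the 2-way mixing coefficient
#'
#' The through-origin least-squares slope of the auxiliary-pair point set:
#' `alpha = sum(response * predictor) / sum(predictor^2)`. Because the
#' projection onto auxiliary-pair directions approximately preserves the
#' donor-hybrid geometry while depleting post-admixture drift (random
#' high-dimensional displacements are nearly orthogonal to any fixed
#' direction), this estimator is more robust to drift than the full-space
#' estimate. With a single usable pair it collapses to the classical
#' f4-ratio.
#'
#' @param point_set An `f4_point_set` from [build_f4_point_set()].
#' @return List with `alpha`, `se`, `ci`, `df`, `n_pairs`.
#' @export
alpha_jl <- function(point_set) {
  stopifnot(inherits(point_set, "f4_point_set"))
  if (nrow(point_set) == 0L) stop("empty point set")
  if (all(point_set$predictor == 0)) {
    stop("no shared drift: all predictors are zero", call. = FALSE)
  }
  fit <- origin_slope(point_set$predictor, point_set$response)
  list(alpha = fit$estimate, se = fit$se, ci = fit$ci, df = fit$df,
       n_pairs = fit$n)
}

#' Admixture angle varphi in the JL subspace
#'
#' The angle at the hybrid vertex after projection onto the auxiliary-pair
#' directions:
#' `cos(varphi) = sum f4'(x,a;i,j) f4'(x,b;i,j) /
#'  sqrt(sum f4'(x,a)^2 sum f4'(x,b)^2)` over usable pairs. Values near
#' 180 degrees indicate a successful reconstruction of the collinear
#' ancestral admixture configuration; this post-projection angle is a far
#' more reliable admixture indicator than the full-space phi because the
#' projection suppresses post-admixture drift.
#'
#' @inheritParams alpha_full_space
#' @param point_set Optionally a prebuilt `f4_point_set` (avoids
#'   recomputation); otherwise built from `panel` and `config`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_varphi <- function(panel, config, point_set = NULL) {
  if (is.null(point_set)) point_set <- build_f4_point_set(panel, config)
  # f4'(x, a; i, j) = f4'(x, b; i, j) - f4'(a, b; i, j), same pair scaling
  fxa <- point_set$response - point_set$predictor
  fxb <- point_set$response
  na2 <- sum(fxa^2)
  nb2 <- sum(fxb^2)
  if (na2 == 0 || nb2 == 0) {
    stop("undefined angle: hybrid coincides with a donor in projection",
         call. = FALSE)
  }
  deg(acos(clamp_cos(sum(fxa * fxb) / sqrt(na2 * nb2))))
}

#' Classical f4-ratio estimate of alpha from a single auxiliary pair
#'
#' `alpha = f4(x, b; i, j) / f4(a, b; i, j)` — the historical single-pair
#' estimator, equivalent to projecting onto one auxiliary-pair direction
#' (a drastic one-dimensional reduction; the pooled estimator [alpha_jl()]
#' is preferred). A pair with negligible shared drift with the donors
#' makes the ratio unreliable and raises an error.
#'
#' @inheritParams alpha_full_space
#' @param x,a,b Hybrid and donor labels.
#' @param i,j Auxiliary pair labels.
#' @param tol Unreliable-ratio threshold on `|f4(a, b; i, j)|`.
#' @return The ratio as a single number.
#' @export
f4_ratio <- function(panel, x, a, b, i, j, tol = 1e-12) {
  denom <- f4(panel, a, b, i, j)
  if (abs(denom) <= tol) {
    stop(sprintf("unreliable ratio: |f4(%s,%s;%s,%s)| = %.3g <= tol (no shared drift)",
                 a, b, i, j, abs(denom)), call. = FALSE)
  }
  f4(panel, x, b, i, j) / denom
}

#' Per-pair diagnostics of the subspace fit
#'
#' The weighted-average decomposition of the subspace slope: each
#' auxiliary pair contributes its single-pair ratio `m_i =
#' response/predictor` with weight `predictor^2`, and the pooled estimate
#' is `sum(m_i w_i) / sum(w_i)`. The table exposes, per pair and sorted by
#' decreasing weight, the predictor, response, ratio (NA when the
#' predictor is too small for a reliable standalone ratio), weight and
#' cumulative weight share — the data behind the recommended 2D
#' regression plot, and the direct way to see which auxiliary pairs drive
#' the estimate.
#'
#' @inheritParams alpha_jl
#' @param ratio_tol Pairs with `|predictor| <= ratio_tol` get `m = NA`.
#' @return A data frame sorted by decreasing weight with columns `pair_i`,
#'   `pair_j`, `predictor`, `response`, `m`, `weight`, `weight_share`,
#'   `cum_weight_share`.
#' @export
pair_diagnostics <- function(point_set, ratio_tol = 1e-8) {
  stopifnot(inherits(point_set, "f4_point_set"))
  d <- as.data.frame(point_set)
  d$m <- ifelse(abs(d$predictor) > ratio_tol, d$response / d$predictor,
                NA_real_)
  total <- sum(d$weight)
  d$weight_share <- if (total > 0) d$weight / total else 0
  d <- d[order(-d$weight), , drop = FALSE]
  d$cum_weight_share <- cumsum(d$weight_share)
  rownames(d) <- NULL
  d[, c("pair_i", "pair_j", "predictor", "response", "m",
        "weight", "weight_share", "cum_weight_share")]
}

#' Fit a 2-way admixture model
#'
#' Runs the complete 2-way analysis: full-space and subspace estimates of
#' the mixing coefficient with confidence intervals, pre- and
#' post-projection admixture angles, and the classical f3 admixture test.
#'
#' @inheritParams alpha_full_space
#' @param tol Degenerate-pair threshold passed to [build_f4_point_set()].
#' @return An `admixture_fit2` object (list) with fields `alpha_full`,
#'   `ci_full`, `alpha_jl`, `ci_jl`, `phi_deg`, `varphi_deg`, `f3_test`,
#'   `test_passed_full`, `n_pairs_used`, `n_pairs_excluded`, `config`.
#' @export
fit_admixture2 <- function(panel, config, tol = 1e-12) {
  full <- alpha_full_space(panel, config)
  ps <- build_f4_point_set(panel, config, tol = tol)
  jl <- alpha_jl(ps)
  test <- admixture_test_full(panel, config)
  out_of_range <- c(full = full$alpha, jl = jl$alpha)
  out_of_range <- out_of_range[out_of_range < 0 | out_of_range > 1]
  if (length(out_of_range) > 0L) {
    warning(sprintf("mixing coefficient %s outside [0, 1]: possible introgression or model misfit",
                    paste(sprintf("%.4f (%s)", out_of_range,
                                  names(out_of_range)), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(alpha_full = full$alpha, ci_full = full$ci,
                 alpha_jl = jl$alpha, ci_jl = jl$ci,
                 phi_deg = test$phi_deg,
                 varphi_deg = angle_varphi(panel, config, point_set = ps),
                 f3_test = test$f3, test_passed_full = test$passed,
                 n_pairs_used = nrow(ps),
                 n_pairs_excluded = attr(ps, "n_excluded"),
                 config = config),
            class = "admixture_fit2")
}

#' @param x An `admixture_fit2`.
#' @param ... Ignored.
#' @rdname fit_admixture2
#' @export
print.admixture_fit2 <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("2-way admixture: %s = alpha * %s + (1 - alpha) * %s\n",
              cfg$hybrid, cfg$donor_a, cfg$donor_b))
  cat(sprintf("  alpha (subspace fit) : %.4f  [%.4f, %.4f]\n",
              x$alpha_jl, x$ci_jl[1], x$ci_jl[2]))
  cat(sprintf("  alpha (full space)   : %.4f  [%.4f, %.4f]\n",
              x$alpha_full, x$ci_full[1], x$ci_full[2]))
  cat(sprintf("  angle phi (full)     : %7.2f deg\n", x$phi_deg))
  cat(sprintf("  angle varphi (JL)    : %7.2f deg (180 = ideal reconstruction)\n",
              x$varphi_deg))
  cat(sprintf("  f3(%s,%s;%s) = %.6g -> admixture test %s\n",
              cfg$donor_a, cfg$donor_b, cfg$hybrid, x$f3_test,
              if (x$test_passed_full) "PASSED" else "NOT passed"))
  cat(sprintf("  auxiliary pairs used : %d (excluded %d degenerate)\n",
              x$n_pairs_used, x$n_pairs_excluded))
  invisible(x)
}
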