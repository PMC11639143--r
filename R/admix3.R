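#' Configuration of a 3-way admixture analysis
#'
#' Names the hybrid, the three donors and the auxiliary populations used
#' to span the projection subspace.
#'
#' @param hybrid Label of the admixed population x.
#' @param donor_a,donor_b,donor_c Labels of the three donors.
#' @param auxiliaries Character vector of k >= 2 auxiliary labels.
#' @return An `admixture_config3` object.
#' @export
admixture_config3 <- function(hybrid, donor_a, donor_b, donor_c, auxiliaries) {
  labels <- c(hybrid, donor_a, donor_b, donor_c, auxiliaries)
  if (anyDuplicated(labels)) {
    stop("hybrid, donors and auxiliaries must be disjoint")
  }
  if (length(auxiliaries) < 2L) {
    stop("at least k = 2 auxiliary populations are required")
  }
  structure(list(hybrid = hybrid, donor_a = donor_a, donor_b = donor_b,
                 donor_c = donor_c,
                 auxiliaries = sort(as.character(auxiliaries))),
            class = "admixture_config3")
}

#' Treeness check for a putative 3-way hybrid
#'
#' A necessary condition for x to be a 3-way hybrid of phylogenetically
#' related donors a, b, c is that the quartet `{x, a, b, c}` is *not* a
#' phylogenetic tree, i.e. the three quartet statistics
#' `f4(x,a;b,c)`, `f4(x,c;a,b)` and `f4(x,b;c,.)` are all nonzero. The
#' published third statistic names a fourth donor that is never defined;
#' by symmetry with the first two it is taken as `f4(x,b;c,a)` (the
#' `third_pop` argument makes the substituted label explicit and
#' overridable).
#'
#' "Nonzero" is judged against `n_sd` times the analytic standard error
#' of each f4 (standard deviation of the per-SNP products divided by
#' sqrt(s)), or against an absolute tolerance if `tol` is given.
#'
#' @param panel A [frequency_panel].
#' @param config An [admixture_config3].
#' @param n_sd Multiple of the analytic SE used as the nonzero threshold.
#' @param tol Optional absolute threshold overriding the SE rule.
#' @param third_pop Population closing the third quartet; default donor a.
#' @return List with `f4` (named vector of the three statistics),
#'   `threshold` (per statistic), and `consistent_with_admixture`.
#' @export
treeness_check <- function(panel, config, n_sd = 3, tol = NULL,
                           third_pop = config$donor_a) {
  x <- config$hybrid; a <- config$donor_a
  b <- config$donor_b; c <- config$donor_c
  quartets <- list(c(x, a, b, c), c(x, c, a, b), c(x, b, c, third_pop))
  names(quartets) <- vapply(quartets, function(q)
    sprintf("f4(%s,%s;%s,%s)", q[1], q[2], q[3], q[4]), character(1))
  s <- n_snps(panel)
  vals <- thr <- numeric(length(quartets))
  for (m in seq_along(quartets)) {
    q <- quartets[[m]]
    terms <- (pop_vector(panel, q[1]) - pop_vector(panel, q[2])) *
             (pop_vector(panel, q[3]) - pop_vector(panel, q[4]))
    vals[m] <- mean(terms)
    thr[m] <- if (is.null(tol)) n_sd * stats::sd(terms) / sqrt(s) else tol
  }
  names(vals) <- names(thr) <- names(quartets)
  list(f4 = vals, threshold = thr,
       consistent_with_admixture = all(abs(vals) > thr))
}

#' Full-phase-space 3-way plane fit
#'
#' Estimates (alpha, beta) in the model `p_x = alpha p_a + beta p_b +
#' (1 - alpha - beta) p_c` by fitting a plane through the origin to the
#' per-SNP set `{p_a - p_c, p_b - p_c, p_x - p_c}`; gamma is reported as
#' the complement `1 - alpha - beta`.
#'
#' @inheritParams treeness_check
#' @return List with `coefficients` (alpha, beta, gamma), `se`, `ci`
#'   (rows alpha/beta/gamma), `df`.
#' @export
fit3_full_space <- function(panel, config) {
  check_pops(panel, c(config$hybrid, config$donor_a, config$donor_b,
                      config$donor_c))
  pc <- pop_vector(panel, config$donor_c)
  X <- cbind(alpha = pop_vector(panel, config$donor_a) - pc,
             beta = pop_vector(panel, config$donor_b) - pc)
  y <- pop_vector(panel, config$hybrid) - pc
  finish_fit3(origin_plane(X, y))
}

#' Build the 3-way auxiliary-pair point set
#'
#' For each usable auxiliary pair (i, j) computes the two predictors
#' `f4'(a, c; i, j)` and `f4'(b, c; i, j)` and the response
#' `f4'(x, c; i, j)`; in the projection subspace the 3-way model is the
#' plane `f4'(x,c) = alpha f4'(a,c) + beta f4'(b,c)` through the origin.
#'
#' @inheritParams treeness_check
#' @param tol Degenerate-pair threshold on f2(i, j).
#' @return Data frame with columns `pair_i`, `pair_j`, `pred_a`, `pred_b`,
#'   `response`; attributes `n_excluded`, `s`, `config`.
#' @export
build_f4_point_set3 <- function(panel, config, tol = 1e-12) {
  aux <- config$auxiliaries
  check_pops(panel, c(config$hybrid, config$donor_a, config$donor_b,
                      config$donor_c, aux))
  s <- n_snps(panel)
  A <- unclass(panel)[, aux, drop = FALSE]
  G <- crossprod(A)
  ssq <- diag(G)
  pc <- pop_vector(panel, config$donor_c)
  vac <- as.vector(crossprod(A, pop_vector(panel, config$donor_a) - pc))
  vbc <- as.vector(crossprod(A, pop_vector(panel, config$donor_b) - pc))
  vxc <- as.vector(crossprod(A, pop_vector(panel, config$hybrid) - pc))
  k <- length(aux)
  ii <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  jj <- sequence((k - 1L):1L) + ii
  f2s <- ssq[ii] + ssq[jj] - 2 * G[cbind(ii, jj)]
  usable <- f2s / s > tol
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    message(sprintf("build_f4_point_set3: excluded %d degenerate auxiliary pair(s)",
                    n_excluded))
  }
  if (sum(usable) < 2L) {
    stop("insufficient pairs: need at least 2 usable auxiliary pairs",
         call. = FALSE)
  }
  ii <- ii[usable]; jj <- jj[usable]; f2s <- f2s[usable]
  out <- data.frame(pair_i = aux[ii], pair_j = aux[jj],
                    pred_a = s * (vac[ii] - vac[jj]) / f2s,
                    pred_b = s * (vbc[ii] - vbc[jj]) / f2s,
                    response = s * (vxc[ii] - vxc[jj]) / f2s,
                    stringsAsFactors = FALSE)
  structure(out, n_excluded = n_excluded, s = s, config = config,
            class = c("f4_point_set3", "data.frame"))
}

#' Subspace (JL) 3-way plane fit
#'
#' Fits the plane through the origin to the 3D auxiliary-pair point set
#' of [build_f4_point_set3()]; as in the 2-way case the projection
#' depletes post-admixture drift, so the recovered (alpha, beta, gamma)
#' are closer to the admixture-inception proportions than the full-space
#' fit when drift is appreciable.
#'
#' @inheritParams build_f4_point_set3
#' @param point_set Optionally a prebuilt point set.
#' @return As [fit3_full_space()], plus `n_pairs`.
#' @export
fit3_jl <- function(panel, config, tol = 1e-12, point_set = NULL) {
  if (is.null(point_set)) point_set <- build_f4_point_set3(panel, config, tol)
  X <- cbind(alpha = point_set$pred_a, beta = point_set$pred_b)
  fit <- finish_fit3(origin_plane(X, point_set$response))
  fit$n_pairs <- nrow(point_set)
  fit
}

# complement gamma = 1 - alpha - beta with propagated SE/CI
finish_fit3 <- function(fit) {
  ab <- unname(fit$estimate)
  gamma <- 1 - sum(ab)
  if (all(is.finite(fit$cov))) {
    se_g <- sqrt(sum(fit$cov))
    half <- stats::qt(0.975, fit$df) * se_g
    ci_g <- c(gamma - half, gamma + half)
  } else {
    se_g <- NA_real_
    ci_g <- c(NA_real_, NA_real_)
  }
  coefs <- c(alpha = ab[1], beta = ab[2], gamma = gamma)
  se <- c(fit$se, gamma = se_g)
  ci <- rbind(fit$ci, gamma = ci_g)
  colnames(ci) <- c("lower", "upper")
  list(coefficients = coefs, se = se, ci = ci, df = fit$df)
}

# flatness 3V / A^(3/2) from a 4x4 squared-distance matrix
# (apex first, then the three base vertices)
flatness_from_d2 <- function(d2, cm_tol = 1e-9) {
  a2 <- d2[2, 3]; b2 <- d2[2, 4]; c2 <- d2[3, 4]
  area2 <- (4 * a2 * b2 - (a2 + b2 - c2)^2) / 16
  if (area2 <= 0) stop("degenerate base triangle (zero area)", call. = FALSE)
  cm <- rbind(c(0, 1, 1, 1, 1),
              cbind(1, d2))
  detcm <- det(cm)
  v2 <- detcm / 288
  if (v2 < 0) {
    if (abs(v2) > cm_tol * area2^(3 / 2)) {
      warning("negative Cayley-Menger determinant beyond tolerance; flatness clamped to 0",
              call. = FALSE)
    }
    v2 <- 0
  }
  3 * sqrt(v2) / area2^(3 / 4)
}

#' Tetrahedron flatness index
#'
#' A dimensionless measure of how far the four points apex/base form a
#' flat (coplanar) configuration: `3 V / A^(3/2)`, the tetrahedron height
#' over the square root of the base area. V is obtained from the six
#' pairwise squared distances via the Cayley-Menger determinant and A
#' from Heron's formula, so only f2-type distances are needed. A value
#' near 0 means the hybrid is nearly coplanar with its three donors, i.e.
#' close to the admixture-inception geometry.
#'
#' In the full phase space the squared distances are the pairwise f2
#' values. In the projection subspace (`space = "jl"`) each population is
#' represented by its coordinates along the auxiliary-pair directions
#' (the f4'-coordinates scaled by 1/sqrt(s)) and distances are taken
#' there; under drift-type noise the projected tetrahedron is flatter
#' than the full-space one.
#'
#' The index is reliable when the tetrahedron is not so warped that the
#' orthogonal projection of the apex falls outside the base triangle;
#' attribute `apex_inside_base` flags this (checked via barycentric
#' coordinates), with a warning when outside.
#'
#' @param panel A [frequency_panel].
#' @param apex Label of the apex population (the hybrid).
#' @param base Character vector of the three base (donor) labels.
#' @param space `"full"` for allele-frequency space, `"jl"` for the
#'   auxiliary-pair subspace.
#' @param auxiliaries Auxiliary labels (required for `space = "jl"`).
#' @param tol Degenerate-pair threshold for the subspace coordinates.
#' @return Nonnegative scalar with attribute `apex_inside_base`.
#' @export
flatness_index <- function(panel, apex, base, space = c("full", "jl"),
                           auxiliaries = NULL, tol = 1e-12) {
  space <- match.arg(space)
  stopifnot(length(base) == 3L)
  pops <- c(apex, base)
  check_pops(panel, pops)
  if (space == "full") {
    d2 <- outer(seq_along(pops), seq_along(pops),
                Vectorize(function(p, q) f2(panel, pops[p], pops[q])))
  } else {
    if (is.null(auxiliaries) || length(auxiliaries) < 2L) {
      stop("space = 'jl' requires >= 2 auxiliary populations")
    }
    coords <- jl_coordinates(panel, pops, auxiliaries, tol = tol)
    d2 <- as.matrix(stats::dist(coords))^2
  }
  idx <- flatness_from_d2(d2)
  inside <- apex_inside_base(d2)
  if (!inside) {
    warning("orthogonal projection of the apex falls outside the base triangle; flatness index may be misleading",
            call. = FALSE)
  }
  attr(idx, "apex_inside_base") <- inside
  idx
}

# coordinates of the named populations along the usable auxiliary-pair
# directions: row per population, column per pair (i < j); differences of
# rows equal f4'(p, q; i, j) / sqrt(s)
jl_coordinates <- function(panel, pops, auxiliaries, tol = 1e-12) {
  aux <- sort(as.character(auxiliaries))
  check_pops(panel, c(pops, aux))
  s <- n_snps(panel)
  A <- unclass(panel)[, aux, drop = FALSE]
  G <- crossprod(A)
  ssq <- diag(G)
  k <- length(aux)
  ii <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  jj <- sequence((k - 1L):1L) + ii
  f2s <- ssq[ii] + ssq[jj] - 2 * G[cbind(ii, jj)]
  usable <- f2s / s > tol
  if (!any(usable)) stop("no usable auxiliary pair", call. = FALSE)
  ii <- ii[usable]; jj <- jj[usable]; f2s <- f2s[usable]
  V <- crossprod(unclass(panel)[, pops, drop = FALSE], A)   # pops x k
  coords <- sqrt(s) * (V[, ii, drop = FALSE] - V[, jj, drop = FALSE]) /
    rep(f2s, each = length(pops))
  rownames(coords) <- pops
  coords
}

# barycentric test: does the orthogonal projection of the apex (row 1)
# onto the base plane (rows 2:4) land inside the base triangle?
apex_inside_base <- function(d2) {
  d12 <- d2[2, 3]; d13 <- d2[2, 4]; d23 <- d2[3, 4]
  e1 <- sqrt(d12)
  if (e1 == 0) return(FALSE)
  x3 <- (d12 + d13 - d23) / (2 * e1)
  y3 <- sqrt(max(d13 - x3^2, 0))
  if (y3 == 0) return(FALSE)
  # apex distances to the three base vertices
  da1 <- d2[1, 2]; da2 <- d2[1, 3]; da3 <- d2[1, 4]
  px <- (da1 + d12 - da2) / (2 * e1)
  py <- (da1 + x3^2 + y3^2 - da3 - 2 * px * x3) / (2 * y3)
  # barycentric coordinates of (px, py) in triangle (0,0), (e1,0), (x3,y3)
  denom <- e1 * y3
  l2 <- (px * y3 - py * x3) / denom
  l3 <- py * e1 / denom
  l1 <- 1 - l2 - l3
  all(c(l1, l2, l3) >= 0)
}

#' Fit a 3-way admixture model
#'
#' Runs the complete 3-way analysis: treeness check, plane fits in the
#' full space and in the auxiliary-pair subspace, and the flatness index
#' in both spaces.
#'
#' @inheritParams build_f4_point_set3
#' @return An `admixture_fit3` object with fields `full`, `jl` (each with
#'   coefficients/se/ci), `flatness_full`, `flatness_jl`, `treeness`,
#'   `n_pairs_used`, `n_pairs_excluded`, `config`.
#' @export
fit_admixture3 <- function(panel, config, tol = 1e-12) {
  ps <- build_f4_point_set3(panel, config, tol = tol)
  full <- fit3_full_space(panel, config)
  jl <- fit3_jl(panel, config, point_set = ps)
  fl_full <- flatness_index(panel, config$hybrid,
                            c(config$donor_a, config$donor_b, config$donor_c),
                            space = "full")
  fl_jl <- flatness_index(panel, config$hybrid,
                          c(config$donor_a, config$donor_b, config$donor_c),
                          space = "jl", auxiliaries = config$auxiliaries,
                          tol = tol)
  structure(list(full = full, jl = jl,
                 flatness_full = as.numeric(fl_full),
                 flatness_jl = as.numeric(fl_jl),
                 treeness = treeness_check(panel, config),
                 n_pairs_used = nrow(ps),
                 n_pairs_excluded = attr(ps, "n_excluded"),
                 config = config),
            class = "admixture_fit3")
}

#' @param x An `admixture_fit3`.
#' @param ... Ignored.
#' @rdname fit_admixture3
#' @export
print.admixture_fit3 <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("3-way admixture: %s = alpha*%s + beta*%s + gamma*%s\n",
              cfg$hybrid, cfg$donor_a, cfg$donor_b, cfg$donor_c))
  show <- function(lab, f) {
    cat(sprintf("  %-10s alpha=%.4f beta=%.4f gamma=%.4f\n", lab,
                f$coefficients["alpha"], f$coefficients["beta"],
                f$coefficients["gamma"]))
  }
  show("subspace:", x$jl)
  show("full:", x$full)
  cat(sprintf("  flatness: %.4f (full) -> %.4f (subspace)\n",
              x$flatness_full, x$flatness_jl))
  cat(sprintf("  treeness: %s\n",
              if (x$treeness$consistent_with_admixture)
                "consistent with admixture" else "tree-like quartet detected"))
  cat(sprintf("  auxiliary pairs used: %d (excluded %d)\n",
              x$n_pairs_used, x$n_pairs_excluded))
  invisible(x)
}
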