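#' Drift tree for synthetic allele-frequency panels
#'
#' A rooted tree given as an edge list; each branch carries the standard
#' deviation of the Gaussian drift accumulated along it (per SNP) and,
#' optionally, the amplitude of a one-off uniform "jump" displacement
#' emulating a sudden event such as a bottleneck (0 = off, the default).
#' Tips become the columns of the simulated panel; populations that share
#' branches share drift, which is what gives auxiliary pairs straddling
#' the donor split their large shared drift with the donors.
#'
#' @param parent,child Character vectors defining the edges; exactly one
#'   node (the root) must never appear as a child.
#' @param sigma Nonnegative per-branch drift standard deviations.
#' @param jump Nonnegative per-branch uniform jump amplitudes (recycled).
#' @return A `drift_tree` (data frame of edges).
#' @export
drift_tree <- function(parent, child, sigma, jump = 0) {
  stopifnot(length(parent) == length(child),
            length(sigma) %in% c(1L, length(parent)))
  if (length(parent) == 0L) stop("empty tree")
  if (any(sigma < 0)) stop("branch sigma must be nonnegative")
  if (any(jump < 0)) stop("jump amplitude must be nonnegative")
  if (anyDuplicated(child)) stop("a node may have only one parent")
  roots <- setdiff(parent, child)
  if (length(roots) != 1L) {
    stop(sprintf("tree must have exactly one root, found: %s",
                 paste(roots, collapse = ", ")))
  }
  edges <- data.frame(parent = as.character(parent),
                      child = as.character(child),
                      sigma = rep_len(as.numeric(sigma), length(parent)),
                      jump = rep_len(as.numeric(jump), length(parent)),
                      stringsAsFactors = FALSE)
  structure(edges, root = roots, class = c("drift_tree", "data.frame"))
}

#' @rdname drift_tree
#' @param tree A `drift_tree`.
#' @export
tree_tips <- function(tree) setdiff(tree$child, tree$parent)

#' Default two-clade drift tree
#'
#' The stock topology used by the simulator: the root splits into two
#' clades, each headed by a long shared branch; donor `a` and roughly
#' half the auxiliaries descend from one clade, donor `b` and the other
#' half from the other, and a few auxiliaries hang directly off the root.
#' Auxiliary pairs with one member per clade then share the two top
#' branches with the (a, b) donor pair — large shared drift — pairs
#' within a clade share none, and pairs involving a root auxiliary are
#' intermediate, reproducing the weight hierarchy that drives the
#' subspace fit.
#'
#' Branch scales are chosen to emulate a continental-scale human SNP
#' panel: top branches sigma = 0.10 (drift variance 0.01) and tip
#' branches sigma = 0.07, giving between-clade f2 distances around
#' 0.02-0.04.
#'
#' @param n_aux Number of auxiliary tips (>= 2); auxiliaries are named
#'   `s1, s2, ...` (clade of donor a), `d1, d2, ...` (clade of donor b)
#'   and `w1, ...` (root).
#' @param donors Names of the donor tips: 2 for a 2-way scenario or 3 for
#'   a 3-way one. With 3 donors, donor b's clade splits into two
#'   subclades (b with part of the `d` auxiliaries, the third donor with
#'   the rest) so that auxiliary pairs straddling the subclade split
#'   share drift with the (b, c) donor direction — without that internal
#'   structure the third mixing coefficient is not identifiable in the
#'   projection subspace.
#' @param sigma_top Drift SD of the shared clade-head branches (and of
#'   the subclade branches in the 3-donor layout).
#' @param sigma_tip Drift SD of each terminal branch.
#' @return A [drift_tree].
#' @export
default_drift_tree <- function(n_aux = 38L, donors = c("a", "b"),
                               sigma_top = 0.10, sigma_tip = 0.07) {
  stopifnot(n_aux >= 2L, length(donors) %in% 2:3)
  n_w <- max(1L, round(n_aux / 5))
  if (n_aux - n_w < 2L) n_w <- n_aux - 2L
  n_left <- ceiling((n_aux - n_w) / 2)
  n_right <- n_aux - n_w - n_left
  left_aux <- paste0("s", seq_len(n_left))
  right_aux <- paste0("d", seq_len(n_right))
  root_aux <- if (n_w > 0L) paste0("w", seq_len(n_w)) else character(0)
  parent <- c("root", "root",
              rep("cladeA", 1L + n_left),
              rep("root", n_w))
  child <- c("cladeA", "cladeB",
             donors[1L], left_aux,
             root_aux)
  sigma <- c(sigma_top, sigma_top,
             rep(sigma_tip, 1L + n_left),
             rep(sigma_tip, n_w))
  if (length(donors) == 2L) {
    parent <- c(parent, rep("cladeB", 1L + n_right))
    child <- c(child, donors[2L], right_aux)
    sigma <- c(sigma, rep(sigma_tip, 1L + n_right))
  } else {
    n_r1 <- ceiling(n_right / 2)
    aux1 <- right_aux[seq_len(n_r1)]
    aux2 <- setdiff(right_aux, aux1)
    parent <- c(parent, "cladeB", "cladeB",
                rep("cladeB1", 1L + length(aux1)),
                rep("cladeB2", 1L + length(aux2)))
    child <- c(child, "cladeB1", "cladeB2",
               donors[2L], aux1,
               donors[3L], aux2)
    sigma <- c(sigma, sigma_top, sigma_top,
               rep(sigma_tip, 1L + length(aux1)),
               rep(sigma_tip, 1L + length(aux2)))
  }
  drift_tree(parent, child, sigma)
}

#' Specification of a synthetic admixture scenario
#'
#' Bundles everything needed to generate one synthetic dataset: panel
#' size, drift tree, donors and mixing proportions for the hybrid, the
#' bounded-uniform post-admixture noise amplitude, and the seed.
#'
#' @param s Number of SNPs.
#' @param tree A [drift_tree]; default [default_drift_tree()] with 38
#'   auxiliaries (a 40-population panel).
#' @param donors Donor tip labels: 2 for a 2-way scenario, 3 for 3-way.
#' @param proportions Mixing proportions, same length as `donors`, in
#'   \[0, 1\] and summing to 1.
#' @param hybrid_name Name of the constructed hybrid column.
#' @param noise_amplitude Post-admixture noise amplitude epsilon in
#'   \[0, 0.5\].
#' @param noise_populations `"focal"` (donors and hybrid, the default) or
#'   an explicit character vector of populations to perturb.
#' @param seed Integer seed, or `NULL` for nondeterministic output.
#' @param ancestral_freq_range Interval within (0, 1) from which ancestral
#'   (root) frequencies are drawn uniformly per SNP; default (0.1, 0.9)
#'   emulates an ascertained common-variant panel.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(s = 50000L, tree = default_drift_tree(),
                            donors = c("a", "b"), proportions = c(0.4, 0.6),
                            hybrid_name = "x", noise_amplitude = 0.1,
                            noise_populations = "focal", seed = NULL,
                            ancestral_freq_range = c(0.1, 0.9)) {
  stopifnot(inherits(tree, "drift_tree"), s >= 1L)
  if (length(donors) != length(proportions) || !length(donors) %in% 2:3) {
    stop("need 2 or 3 donors with matching proportions")
  }
  if (any(proportions < 0 | proportions > 1) ||
      abs(sum(proportions) - 1) > 1e-12) {
    stop("proportions must lie in [0, 1] and sum to 1")
  }
  if (noise_amplitude < 0 || noise_amplitude > 0.5) {
    stop("noise_amplitude must lie in [0, 0.5]")
  }
  if (!all(donors %in% tree_tips(tree))) {
    stop("donors must be tips of the tree")
  }
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      diff(ancestral_freq_range) <= 0) {
    stop("ancestral_freq_range must be an increasing interval within (0, 1)")
  }
  structure(list(s = as.integer(s), tree = tree, donors = donors,
                 proportions = proportions, hybrid_name = hybrid_name,
                 noise_amplitude = noise_amplitude,
                 noise_populations = noise_populations,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 ancestral_freq_range = ancestral_freq_range),
            class = "simulation_spec")
}

# fold values back into [0, 1] (reflection at both boundaries)
reflect01 <- function(x) {
  y <- x %% 2
  ifelse(y > 1, 2 - y, y)
}

#' Simulate a tree-structured allele-frequency panel
#'
#' Draws ancestral frequencies uniformly per SNP, then propagates them
#' down the drift tree: each branch adds independent Gaussian increments
#' with its branch standard deviation (plus an optional uniform jump),
#' reflected back into \[0, 1\] at the boundaries. Tips become panel
#' columns; the hybrid is *not* part of the simulated panel — build it
#' with [make_hybrid()].
#'
#' @param spec A [simulation_spec]; its `seed` (if non-NULL) makes the
#'   panel reproducible.
#' @return A [frequency_panel] with one column per tree tip.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  tree <- spec$tree
  s <- spec$s
  values <- list()
  values[[attr(tree, "root")]] <-
    stats::runif(s, spec$ancestral_freq_range[1], spec$ancestral_freq_range[2])
  pending <- tree
  while (nrow(pending) > 0L) {
    ready <- pending$parent %in% names(values)
    if (!any(ready)) stop("tree is not connected from the root")
    for (e in which(ready)) {
      v <- values[[pending$parent[e]]] +
        stats::rnorm(s, 0, pending$sigma[e])
      if (pending$jump[e] > 0) {
        v <- v + stats::runif(s, -pending$jump[e], pending$jump[e])
      }
      values[[pending$child[e]]] <- reflect01(v)
    }
    pending <- pending[!ready, , drop = FALSE]
  }
  tips <- tree_tips(tree)
  frequency_panel(do.call(cbind, values[tips]), pop_names = tips)
}

#' Append an exact linear hybrid to a panel
#'
#' Adds a column that is, SNP by SNP, the exact convex combination of the
#' donor columns with the given proportions — the admixture-inception
#' state before any post-admixture drift.
#'
#' @param panel A [frequency_panel].
#' @param donors Donor labels (2 or 3).
#' @param proportions Mixing proportions in \[0, 1\] summing to 1.
#' @param name Name of the new hybrid column.
#' @return The extended [frequency_panel].
#' @export
make_hybrid <- function(panel, donors, proportions, name = "x") {
  stopifnot(is_frequency_panel(panel),
            length(donors) == length(proportions))
  check_pops(panel, donors)
  if (any(proportions < 0 | proportions > 1) ||
      abs(sum(proportions) - 1) > 1e-12) {
    stop("proportions must lie in [0, 1] and sum to 1")
  }
  if (name %in% pop_names(panel)) {
    stop(sprintf("population '%s' already present", name))
  }
  hyb <- as.vector(unclass(panel)[, donors, drop = FALSE] %*% proportions)
  frequency_panel(cbind(unclass(panel), hyb),
                  snp_ids = snp_ids(panel),
                  pop_names = c(pop_names(panel), name))
}

#' Add bounded uniform post-admixture noise
#'
#' Emulates post-admixture drift: to every frequency of the named
#' populations adds `epsilon * delta` with `delta` uniform on \[-1, 1\],
#' redrawing `delta` for any entry whose perturbed frequency falls
#' outside \[0, 1\] until all entries are in range (the rejection always
#' terminates for epsilon <= 0.5). Other populations are untouched.
#'
#' @param panel A [frequency_panel].
#' @param populations Labels of the populations to perturb.
#' @param epsilon Noise amplitude in \[0, 0.5\].
#' @param seed Optional integer seed.
#' @return The perturbed [frequency_panel].
#' @export
add_post_admixture_noise <- function(panel, populations, epsilon,
                                     seed = NULL) {
  stopifnot(is_frequency_panel(panel))
  check_pops(panel, populations)
  if (epsilon < 0 || epsilon > 0.5) stop("epsilon must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  if (epsilon == 0 || length(populations) == 0L) return(panel)
  M <- unclass(panel)[, populations, drop = FALSE]
  out <- M + epsilon * stats::runif(length(M), -1, 1)
  bad <- which(out < 0 | out > 1)
  while (length(bad) > 0L) {
    out[bad] <- M[bad] + epsilon * stats::runif(length(bad), -1, 1)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  full <- unclass(panel)
  full[, populations] <- out
  frequency_panel(full, snp_ids = snp_ids(panel),
                  pop_names = pop_names(panel))
}

#' Run a replicate recovery experiment
#'
#' The simulation protocol used to validate the estimators: per
#' replicate, simulate a panel, append the exact hybrid, perturb the
#' focal populations with bounded uniform noise, then estimate the mixing
#' proportions with both the full-phase-space and the subspace estimator,
#' recording angles (2-way) or flatness indices (3-way). Replicate seeds
#' are `spec$seed + 1 ... spec$seed + n_replicates` when a seed is set.
#'
#' @param spec A [simulation_spec].
#' @param n_replicates Number of replicates (>= 1).
#' @return A `recovery_experiment` list: `replicates` (one row per
#'   replicate) and `summary` (means, SDs and mean absolute / relative
#'   errors against the nominal proportions).
#' @export
run_recovery_experiment <- function(spec, n_replicates = 50L) {
  stopifnot(inherits(spec, "simulation_spec"), n_replicates >= 1L)
  three_way <- length(spec$donors) == 3L
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rspec <- spec
    if (!is.null(spec$seed)) rspec$seed <- spec$seed + r
    panel <- simulate_panel(rspec)
    panel <- make_hybrid(panel, spec$donors, spec$proportions,
                         name = spec$hybrid_name)
    noise_pops <- if (identical(spec$noise_populations, "focal")) {
      c(spec$donors, spec$hybrid_name)
    } else spec$noise_populations
    panel <- add_post_admixture_noise(panel, noise_pops,
                                      spec$noise_amplitude)
    aux <- setdiff(pop_names(panel), c(spec$donors, spec$hybrid_name))
    if (three_way) {
      cfg <- admixture_config3(spec$hybrid_name, spec$donors[1],
                               spec$donors[2], spec$donors[3], aux)
      full <- fit3_full_space(panel, cfg)
      jl <- fit3_jl(panel, cfg)
      base <- spec$donors
      rows[[r]] <- data.frame(
        replicate = r,
        alpha_full = full$coefficients[["alpha"]],
        beta_full = full$coefficients[["beta"]],
        gamma_full = full$coefficients[["gamma"]],
        alpha_jl = jl$coefficients[["alpha"]],
        beta_jl = jl$coefficients[["beta"]],
        gamma_jl = jl$coefficients[["gamma"]],
        flatness_full = as.numeric(
          suppressWarnings(flatness_index(panel, spec$hybrid_name, base))),
        flatness_jl = as.numeric(
          suppressWarnings(flatness_index(panel, spec$hybrid_name, base,
                                          space = "jl", auxiliaries = aux))))
    } else {
      cfg <- admixture_config2(spec$hybrid_name, spec$donors[1],
                               spec$donors[2], aux)
      ps <- build_f4_point_set(panel, cfg)
      rows[[r]] <- data.frame(
        replicate = r,
        alpha_full = alpha_full_space(panel, cfg)$alpha,
        alpha_jl = alpha_jl(ps)$alpha,
        phi_deg = angle_phi(panel, cfg),
        varphi_deg = angle_varphi(panel, cfg, point_set = ps))
    }
  }
  reps <- do.call(rbind, rows)
  nominal <- spec$proportions
  if (three_way) {
    est_jl <- reps[, c("alpha_jl", "beta_jl", "gamma_jl")]
    est_full <- reps[, c("alpha_full", "beta_full", "gamma_full")]
    summary <- data.frame(
      noise_amplitude = spec$noise_amplitude,
      n_replicates = n_replicates,
      mean_alpha_jl = mean(reps$alpha_jl),
      mean_beta_jl = mean(reps$beta_jl),
      mean_gamma_jl = mean(reps$gamma_jl),
      sd_beta_jl = stats::sd(reps$beta_jl),
      mae_jl = mean(rowMeans(abs(sweep(as.matrix(est_jl), 2, nominal)))),
      mae_full = mean(rowMeans(abs(sweep(as.matrix(est_full), 2, nominal)))),
      mean_flatness_full = mean(reps$flatness_full),
      mean_flatness_jl = mean(reps$flatness_jl))
  } else {
    a0 <- nominal[1]
    summary <- data.frame(
      noise_amplitude = spec$noise_amplitude,
      nominal_alpha = a0,
      n_replicates = n_replicates,
      mean_alpha_jl = mean(reps$alpha_jl),
      mean_alpha_full = mean(reps$alpha_full),
      sd_alpha_jl = stats::sd(reps$alpha_jl),
      mae_jl = mean(abs(reps$alpha_jl - a0)),
      mae_full = mean(abs(reps$alpha_full - a0)),
      mean_rel_err_jl = mean(abs(reps$alpha_jl - a0)) / a0,
      mean_rel_err_full = mean(abs(reps$alpha_full - a0)) / a0,
      mean_phi_deg = mean(reps$phi_deg),
      mean_varphi_deg = mean(reps$varphi_deg))
  }
  structure(list(replicates = reps, summary = summary, spec = spec),
            class = "recovery_experiment")
}

#' @param x A `recovery_experiment`.
#' @param ... Ignored.
#' @rdname run_recovery_experiment
#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("<recovery_experiment> %d replicate(s), %d-way admixture, eps = %g\n",
              nrow(x$replicates), length(x$spec$donors),
              x$spec$noise_amplitude))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
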