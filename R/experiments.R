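#' Dense-data recovery experiment
#'
#' Simulates one smooth ground-truth curve and a dense contact matrix from
#' it (large `b` means ample contact information), then runs independent
#' single-scale optimizations from many random initializations with small
#' penalty weights and no bulk prior. With dense data the best solutions
#' recover the truth almost exactly, while other near-optimal local minima
#' differ by local reflections — so RMSD to truth and energy are only
#' loosely correlated.
#'
#' @param n bins per curve; default 100.
#' @param b Poisson scale; default 1e6 (dense regime).
#' @param n_inits number of random initializations; default 20.
#' @param seed master seed.
#' @param a power-law exponent.
#' @param lambda1,lambda2 small penalty weights; default 0.001.
#' @return a list of class `"experiment_report"`: `table` (one row per
#'   initialization: `seed`, `rmsd`, `energy`, ordered by ascending RMSD),
#'   `pairwise` (RMSD matrix in the same order), `truth`, `curves`,
#'   `rg_truth` (radius of gyration of the truth).
#' @export
run_dense_recovery <- function(n = 100, b = 1e6, n_inits = 20, seed = 1,
                               a = -3, lambda1 = 0.001, lambda2 = 0.001) {
  gt <- generate_ground_truth_ensemble(n = n, K = 1, variability = 0,
                                       seed = seed)
  truth <- gt$mean_curve
  C <- simulate_contact_matrix(truth, a = a, b = b, seed = seed)
  params <- model_params(a = a, b = 1, lambda1 = lambda1, lambda2 = lambda2,
                         lambda3 = 0)
  init_seeds <- cell_seed(seed, seq_len(n_inits))
  fits <- lapply(init_seeds, function(s) {
    optimize_single_scale(C, params = params, X_init = random_init(n, s))
  })
  tab <- data.frame(
    seed = init_seeds,
    rmsd = vapply(fits, function(f) rmsd_to_reference(f$curve, truth),
                  numeric(1)),
    energy = vapply(fits, function(f) f$energy, numeric(1)))
  ord <- order(tab$rmsd)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  curves <- lapply(fits[ord], `[[`, "curve")
  structure(list(experiment = "dense_recovery", table = tab,
                 pairwise = pairwise_rmsd(curves), truth = truth,
                 curves = curves, rg_truth = radius_of_gyration(truth),
                 seed = seed),
            class = "experiment_report")
}

#' Bulk-prior sweep on sparse data
#'
#' Simulates a `K`-cell ensemble of ground-truth curves and sparse contact
#' matrices (small `b`), then estimates the first `n_cells` structures for
#' each value of `lambda3` in the grid, using the leave-one-out sum of the
#' other `K - 1` matrices as the bulk prior. The same initialization seeds
#' are reused across `lambda3` values, so the `lambda3 = 0` column is
#' exactly a prior-free run. Mean aligned RMSD to the per-cell truth as a
#' function of `lambda3` quantifies the benefit of the population prior;
#' on sparse data it drops as soon as `lambda3` leaves 0.
#'
#' @param K ensemble size used for the leave-one-out bulk; default 100.
#' @param lambda3_grid values of the prior weight to sweep, including 0.
#' @param n_cells number of cells to reconstruct; default 8.
#' @param n_inits random initializations per cell and `lambda3`; default 5.
#' @param seed master seed.
#' @param n bins per curve; default 100.
#' @param b Poisson scale; default 10 (sparse regime).
#' @param lambda12 shared value for the spacing and smoothness weights;
#'   default 0.1.
#' @param variability ensemble shape variability; default 0.2.
#' @return a list of class `"experiment_report"`: `table` (rows: cell,
#'   lambda3, init seed, rmsd, energy) and `summary` (mean RMSD per
#'   lambda3).
#' @export
run_prior_sweep <- function(K = 100, lambda3_grid = c(0, 0.1, 0.25, 0.5, 1),
                            n_cells = 8, n_inits = 5, seed = 1, n = 100,
                            b = 10, lambda12 = 0.1, variability = 0.2) {
  if (!0 %in% lambda3_grid) lambda3_grid <- c(0, lambda3_grid)
  if (n_cells > K) stop("n_cells cannot exceed K")
  gt <- generate_ground_truth_ensemble(n = n, K = K,
                                       variability = variability,
                                       seed = seed)
  mats <- lapply(seq_len(K), function(k) {
    simulate_contact_matrix(gt$curves[[k]], a = -3, b = b,
                            seed = cell_seed(seed, 7000 + k))
  })
  rows <- list()
  for (cell in seq_len(n_cells)) {
    bulk <- sum_bulk(mats, exclude_index = cell)
    truth <- gt$curves[[cell]]
    init_seeds <- cell_seed(seed, 900 * cell + seq_len(n_inits))
    inits <- lapply(init_seeds, function(s) random_init(n, s))
    for (l3 in lambda3_grid) {
      params <- model_params(a = -3, b = 1, lambda1 = lambda12,
                             lambda2 = lambda12, lambda3 = l3)
      for (i in seq_len(n_inits)) {
        fit <- optimize_single_scale(mats[[cell]],
                                     C_bulk = if (l3 > 0) bulk else NULL,
                                     params = params, X_init = inits[[i]])
        rows[[length(rows) + 1]] <- data.frame(
          cell = cell, lambda3 = l3, seed = init_seeds[i],
          rmsd = rmsd_to_reference(fit$curve, truth), energy = fit$energy)
      }
    }
  }
  tab <- do.call(rbind, rows)
  summ <- stats::aggregate(rmsd ~ lambda3, data = tab, FUN = mean)
  structure(list(experiment = "prior_sweep", table = tab, summary = summ,
                 K = K, seed = seed),
            class = "experiment_report")
}

#' Multiscale versus flat optimization comparison
#'
#' For each of `n_seeds` simulated problems, runs the full coarse-to-fine
#' pipeline and a flat single-scale optimization from the same random
#' seed, and records the paired difference in final energy
#' (flat minus multiscale). A positive mean difference indicates that the
#' coarse-to-fine path reaches lower-energy solutions on average.
#'
#' @param n bins per curve; default 128.
#' @param n_seeds number of paired runs; default 10.
#' @param seed master seed.
#' @param b Poisson scale of the simulated data; default 10 (sparse data,
#'   where local optima are plentiful).
#' @param min_n coarsening floor for the multiscale arm; default 32.
#' @param lambda1,lambda2 penalty weights; defaults (0.5, 1).
#' @return a list of class `"experiment_report"`: `table` (per-seed
#'   energies in both arms and their difference) and `summary` (mean
#'   difference and sign counts).
#' @export
run_multiscale_comparison <- function(n = 128, n_seeds = 10, seed = 1,
                                      b = 10, min_n = 32,
                                      lambda1 = 0.5, lambda2 = 1) {
  gt <- generate_ground_truth_ensemble(n = n, K = 1, variability = 0,
                                       seed = seed)
  C <- simulate_contact_matrix(gt$mean_curve, a = -3, b = b, seed = seed)
  params <- model_params(a = -3, b = 1, lambda1 = lambda1, lambda2 = lambda2,
                         lambda3 = 0)
  run_seeds <- cell_seed(seed, 300 + seq_len(n_seeds))
  rows <- lapply(run_seeds, function(s) {
    multi <- estimate_structure(C, params = params, min_n = min_n,
                                seed = s, multiscale = TRUE)
    flat <- estimate_structure(C, params = params, seed = s,
                               multiscale = FALSE)
    data.frame(seed = s, energy_multiscale = multi$energy,
               energy_flat = flat$energy,
               difference = flat$energy - multi$energy)
  })
  tab <- do.call(rbind, rows)
  summ <- list(mean_difference = mean(tab$difference),
               n_positive = sum(tab$difference > 0),
               n_seeds = n_seeds)
  structure(list(experiment = "multiscale_comparison", table = tab,
                 summary = summ, seed = seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", x$experiment, "\n")
  if (!is.null(x$summary)) {
    if (is.data.frame(x$summary)) print(x$summary) else utils::str(x$summary)
  } else {
    cat(sprintf("  %d runs, best rmsd = %.4g\n", nrow(x$table),
                min(x$table$rmsd)))
  }
  invisible(x)
}

#' Plot an experiment report
#'
#' Dense recovery: RMSD and energy against solution index plus the pairwise
#' RMSD heatmap. Prior sweep: mean RMSD against the prior weight.
#' Multiscale comparison: per-seed paired energy differences.
#'
#' @param x `experiment_report` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.experiment_report <- function(x, ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (x$experiment == "dense_recovery") {
    graphics::par(mfrow = c(1, 3))
    plot(x$table$rmsd, xlab = "solution index (by RMSD)", ylab = "RMSD",
         main = "RMSD to ground truth")
    plot(x$table$energy, xlab = "solution index (by RMSD)",
         ylab = "energy", main = "Final energy")
    graphics::image(x$pairwise, main = "Pairwise RMSD", axes = FALSE,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  } else if (x$experiment == "prior_sweep") {
    plot(x$summary$lambda3, x$summary$rmsd, type = "b",
         xlab = "prior weight", ylab = "mean RMSD",
         main = "Bulk-prior benefit on sparse data")
  } else {
    plot(x$table$difference, xlab = "paired run",
         ylab = "energy(flat) - energy(multiscale)",
         main = "Multiscale benefit")
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
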