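#' Define a parameter sweep
#'
#' Cartesian product of the supplied axes (`rho`, `omega`, `L`) times the
#' number of replicates, each run with a distinct seed derived from
#' `base$seed`.
#'
#' @param base a [sim_params()] object providing every non-swept value.
#' @param rho,omega,L numeric vectors of axis values; `NULL` keeps the
#'   base value (an axis of length 1).
#' @param replicates runs per cell.
#' @param seeds optional vector of seeds, one per run (length
#'   `n_cells * replicates`); derived deterministically when `NULL`.
#' @param burn_in fraction of each run discarded before averaging.
#' @param out_dir directory for per-run results and the manifest; `NULL`
#'   keeps everything in memory (no resume).
#' @return object of class `cav_sweep_spec` with a `grid` data frame
#'   enumerating all runs.
#' @export
sweep_spec <- function(base, rho = NULL, omega = NULL, L = NULL,
                       replicates = 8L, seeds = NULL,
                       burn_in = base$burn_in, out_dir = NULL) {
  stopifnot(inherits(base, "cav_params"))
  ax <- list(rho = if (is.null(rho)) base$rho else rho,
             omega = if (is.null(omega)) base$omega else omega,
             L = if (is.null(L)) base$L else L)
  cells <- expand.grid(rho = ax$rho, omega = ax$omega, L = ax$L,
                       KEEP.OUT.ATTRS = FALSE)
  grid <- cells[rep(seq_len(nrow(cells)), each = replicates), , drop = FALSE]
  grid$replicate <- rep(seq_len(replicates), times = nrow(cells))
  n_runs <- nrow(grid)
  if (is.null(seeds))
    seeds <- base$seed + 1000L * seq_len(n_runs)
  if (length(seeds) != n_runs || anyDuplicated(seeds))
    stop("need one distinct seed per run")
  grid$seed <- as.integer(seeds)
  rownames(grid) <- NULL
  structure(list(base = base, grid = grid, replicates = replicates,
                 burn_in = burn_in, out_dir = out_dir),
            class = "cav_sweep_spec")
}

# observables of one finished run, as a flat named list
.run_observables <- function(traj, burn_in) {
  p <- traj$params
  mlast <- matrix(traj$mem_unwrapped[, , n_frames(traj)], ncol = 2)
  blmax <- max(sqrt(rowSums((mlast[c(2:p$L, 1), , drop = FALSE] - mlast)^2)))
  if (blmax > 3 * p$sigma)
    stop(sprintf("membrane ruptured (max bond %.3g sigma)", blmax))
  rot <- cumulative_rotation(traj)
  op <- mean_angular_velocity(rot, burn_in = burn_in)
  idx <- .after_burn_in(traj, burn_in)
  deltas <- vapply(idx, function(k)
    asphericity(matrix(traj$mem_unwrapped[, , k], ncol = 2))$Delta, numeric(1))
  dphi <- interior_angle_fluctuation(traj, burn_in = burn_in)
  mf <- membrane_force_stats(traj, burn_in = burn_in)
  deff <- tryCatch({
    msd <- com_msd(traj)
    fit_deff(msd, p$N, p$L, p$V0, p$Dtheta, p$omega)$Deff
  }, error = function(e) NA_real_)
  list(omega_prime = op$omega_prime, Delta = mean(deltas),
       DeltaPhi = dphi$DeltaPhi, N_s = mf$N_s, F_tau = mf$F_tau,
       P_n = mf$P_n, Deff = deff)
}

#' Execute a parameter sweep
#'
#' Runs every cell of the sweep, aggregates the per-run observables
#' (vesicle angular velocity, asphericity, interior-angle fluctuation,
#' stacked count, tangential force, pressure, effective diffusion
#' coefficient) into one tidy table with means, standard errors and run
#' counts per `(L, rho, omega)` cell.  With an `out_dir`, each finished
#' run is written as JSON and already-present runs are skipped, so an
#' interrupted sweep resumes and a finished sweep is idempotent.
#'
#' @param spec a [sweep_spec()].
#' @param verbose log per-run progress to stderr.
#' @return data frame with one row per cell.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "cav_sweep_spec"))
  grid <- spec$grid
  use_disk <- !is.null(spec$out_dir)
  if (use_disk && !dir.exists(spec$out_dir))
    dir.create(spec$out_dir, recursive = TRUE)
  runs <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    tag <- sprintf("run_L%d_rho%s_omega%s_rep%d.json",
                   grid$L[r], format(grid$rho[r]), format(grid$omega[r]),
                   grid$replicate[r])
    fp <- if (use_disk) file.path(spec$out_dir, tag) else NULL
    if (use_disk && file.exists(fp)) {
      runs[[r]] <- jsonlite::read_json(fp, simplifyVector = TRUE)
      next
    }
    res <- tryCatch({
      p <- spec$base
      p$rho <- grid$rho[r]
      p$omega <- grid$omega[r]
      pr <- sim_params(L = grid$L[r], rho = grid$rho[r], V0 = p$V0,
                       omega = grid$omega[r], D0 = p$D0, Dtheta = p$Dtheta,
                       gamma = p$gamma, ks = p$ks, r0 = p$r0,
                       sigma = p$sigma, eps = p$eps, dt = p$dt, box = p$box,
                       seed = grid$seed[r], n_steps = p$n_steps,
                       sample_every = p$sample_every, burn_in = spec$burn_in,
                       wca_bonded_neighbors = p$wca_bonded_neighbors,
                       translational_noise = p$translational_noise)
      traj <- run_simulation(pr)
      if (verbose)
        message(sprintf("run %d/%d done (L=%d rho=%g omega=%g seed=%d)",
                        r, nrow(grid), grid$L[r], grid$rho[r],
                        grid$omega[r], grid$seed[r]))
      .run_observables(traj, spec$burn_in)
    }, error = function(e) {
      warning(sprintf("run %d failed: %s", r, conditionMessage(e)))
      list(omega_prime = NA_real_, Delta = NA_real_, DeltaPhi = NA_real_,
           N_s = NA_real_, F_tau = NA_real_, P_n = NA_real_,
           Deff = NA_real_, failed = TRUE)
    })
    runs[[r]] <- res
    if (use_disk)
      jsonlite::write_json(res, fp, auto_unbox = TRUE, digits = NA)
  }
  obs_names <- c("omega_prime", "Delta", "DeltaPhi", "N_s", "F_tau",
                 "P_n", "Deff")
  cells <- unique(grid[, c("L", "rho", "omega")])
  rownames(cells) <- NULL
  out <- cells
  for (nm in obs_names) {
    out[[nm]] <- NA_real_
    out[[paste0(nm, "_se")]] <- NA_real_
  }
  out$n_runs <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- which(grid$L == cells$L[i] & grid$rho == cells$rho[i] &
                 grid$omega == cells$omega[i])
    for (nm in obs_names) {
      v <- vapply(runs[sel], function(x) as.numeric(x[[nm]]), numeric(1))
      v <- v[is.finite(v)]
      out[[nm]][i] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(nm, "_se")]][i] <-
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }
    out$n_runs[i] <- sum(vapply(runs[sel], function(x)
      is.finite(as.numeric(x$omega_prime)), logical(1)))
  }
  if (use_disk) {
    manifest <- file.path(spec$out_dir, "manifest.json")
    jsonlite::write_json(
      list(n_runs = nrow(grid), cells = nrow(cells),
           burn_in = spec$burn_in, seeds = grid$seed),
      manifest, auto_unbox = TRUE, digits = NA)
    utils::write.csv(out, file.path(spec$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}
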