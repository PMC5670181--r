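#' Write a trajectory as extended XYZ
#'
#' One block per frame: a count line, a comment line carrying
#' `time=... U=...`, then one row per particle with columns
#' `species x y theta ux uy` (species `MEM` or `ACT`; `theta` is 0 for
#' membrane monomers; `ux uy` are the unwrapped coordinates).  Values are
#' written with 17 significant digits so a read round-trips bit-exactly.
#'
#' @param traj a `cav_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  L <- dim(traj$mem)[1]
  N <- dim(traj$act)[1]
  f <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  fm <- function(x) sprintf("%.17g", x)
  for (k in seq_len(f)) {
    writeLines(as.character(L + N), con)
    writeLines(sprintf("time=%s U=%s", fm(traj$times[k]), fm(traj$U[k])), con)
    if (L > 0) {
      m <- matrix(traj$mem[, , k], ncol = 2)
      mu <- matrix(traj$mem_unwrapped[, , k], ncol = 2)
      writeLines(paste("MEM", fm(m[, 1]), fm(m[, 2]), fm(rep(0, L)),
                       fm(mu[, 1]), fm(mu[, 2])), con)
    }
    if (N > 0) {
      a <- matrix(traj$act[, , k], ncol = 2)
      au <- matrix(traj$act_unwrapped[, , k], ncol = 2)
      writeLines(paste("ACT", fm(a[, 1]), fm(a[, 2]), fm(traj$theta[, k]),
                       fm(au[, 1]), fm(au[, 2])), con)
    }
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' Inverse of [write_xyz()].  Per-frame active-on-membrane forces are not
#' part of the format, so `fmem_act` is zero-filled; observables that need
#' it ([membrane_force_stats()]) require an in-memory trajectory from
#' [run_simulation()].
#'
#' @param path file written by [write_xyz()].
#' @param params optional [sim_params()] attached to the result (needed by
#'   burn-in defaults and curvature normalisation); when `NULL` a minimal
#'   parameter set is inferred from the frame contents.
#' @return a `cav_trajectory`.
#' @export
read_xyz <- function(path, params = NULL) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    t <- as.numeric(sub(".*time=([^ ]+).*", "\\1", hdr))
    U <- as.numeric(sub(".*U=([^ ]+).*", "\\1", hdr))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(block, " ", fixed = TRUE)
    sp <- vapply(parts, `[[`, "", 1L)
    num <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:6))), ncol = 5,
                  byrow = TRUE)
    frames[[length(frames) + 1L]] <- list(t = t, U = U, sp = sp, num = num)
    i <- i + 2L + n
  }
  f <- length(frames)
  sp <- frames[[1]]$sp
  L <- sum(sp == "MEM")
  N <- sum(sp == "ACT")
  mem <- array(0, c(L, 2, f)); memu <- array(0, c(L, 2, f))
  act <- array(0, c(N, 2, f)); actu <- array(0, c(N, 2, f))
  theta <- matrix(0, N, f)
  times <- Us <- numeric(f)
  for (k in seq_len(f)) {
    fr <- frames[[k]]
    times[k] <- fr$t
    Us[k] <- fr$U
    mi <- fr$sp == "MEM"; ai <- fr$sp == "ACT"
    mem[, , k] <- fr$num[mi, 1:2]
    memu[, , k] <- fr$num[mi, 4:5]
    act[, , k] <- fr$num[ai, 1:2]
    actu[, , k] <- fr$num[ai, 4:5]
    theta[, k] <- fr$num[ai, 3]
  }
  if (is.null(params)) {
    params <- if (L >= 3) sim_params(L = L, N = N) else
      structure(list(L = L, N = N, rho = 0, R0 = NA_real_, V0 = 0.5,
                     omega = 0, D0 = 0.01, Dtheta = 0.03, gamma = 100,
                     ks = 4000, r0 = 1, sigma = 1, eps = 1, dt = 0.01,
                     box = 200, seed = 1L, n_steps = 0,
                     sample_every = 1L, burn_in = 0.5,
                     wca_bonded_neighbors = TRUE,
                     translational_noise = TRUE), class = "cav_params")
  }
  structure(list(times = times, mem = mem, act = act,
                 mem_unwrapped = memu, act_unwrapped = actu, theta = theta,
                 fmem_act = array(0, c(L, 2, f)), U = Us,
                 min_dist = rep(NA_real_, f), params = params,
                 seed = params$seed), class = "cav_trajectory")
}

#' Write per-frame scalars as CSV
#'
#' Sidecar table with one row per frame: time, potential energy and
#' gyration radius.
#'
#' @param traj a `cav_trajectory`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_frame_scalars <- function(traj, path) {
  f <- n_frames(traj)
  rg <- vapply(seq_len(f), function(k)
    asphericity(matrix(traj$mem_unwrapped[, , k], ncol = 2))$Rg, numeric(1))
  utils::write.csv(data.frame(t = traj$times, U = traj$U, Rg = rg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a flat TOML configuration
#'
#' Minimal reader for the subset of TOML used by the configuration files:
#' `key = value` pairs with `#` comments, numbers, booleans and quoted
#' strings; `[section]` headers are accepted and flattened (keys keep only
#' their own name, mirroring the parameter list).  This is deliberately a
#' small hand-rolled reader: no TOML package is available in the target
#' installation, and the configuration grammar is flat.
#'
#' @param path TOML file.
#' @return named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("config parse error: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <-
      if (val %in% c("true", "false")) identical(val, "true")
      else if (grepl('^".*"$', val)) gsub('^"|"$', "", val)
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("config parse error: unrecognised value ", val)
        num
      }
  }
  out
}

#' Build simulation parameters from a configuration list
#'
#' Unknown keys raise an error; every omitted key keeps the [sim_params()]
#' default, so an empty configuration reproduces the reference parameter
#' regime.
#'
#' @param cfg named list, e.g. from [read_config()].
#' @return a [sim_params()] object.
#' @export
params_from_config <- function(cfg) {
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  do.call(sim_params, cfg)
}
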