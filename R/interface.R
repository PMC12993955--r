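#' Single-locus convergence study
#'
#' Runs the noise-free single-locus population, estimates the average
#' effect by per-time regression, and compares it with the additive value
#' and with the sensitivity-based linear prediction \eqn{s(t)\gamma}.
#'
#' @param seed integer seed.
#' @param gamma per-allele effect.
#' @param trait_index trait analysed (default 1, gene-1 expression).
#' @param t_window time window (inclusive) over which relative deviations
#'   are summarised.
#' @return List with `max_abs_dev_alpha_vs_a` (regression slope vs additive
#'   value), `max_rel_dev_alpha_vs_slin` and `mean_rel_dev_alpha_vs_slin`
#'   (slope vs \eqn{s\gamma}, over the window), plus the underlying
#'   estimates.
#' @export
driver_single_locus <- function(seed = 1, gamma = 1e-2, trait_index = 1,
                                t_window = c(5, 50)) {
  sc <- scenario_single_locus(seed = seed, gamma = gamma)
  est <- static_average_effects(sc$series, trait_index = trait_index)
  # genotypic-value trajectories realized in this (noise-free) population
  codes <- sc$series$genotypes$codes[, 1]
  gtraj <- function(code) {
    idx <- which(codes == code)[1]
    new_trajectory(sc$series$times, sc$series$true_states[idx, , ])
  }
  ec <- effect_curves(gtraj(-1), gtraj(0), gtraj(1), q = 0.5)
  truth_lin <- sc$truth[, trait_index, 1]
  in_win <- sc$grid$times >= t_window[1] & sc$grid$times <= t_window[2]
  rel <- abs(est$alpha_s[in_win, 1] - truth_lin[in_win]) /
    abs(truth_lin[in_win])
  list(max_abs_dev_alpha_vs_a =
         max(abs(est$alpha_s[, 1] - ec$a[, trait_index])),
       max_rel_dev_alpha_vs_slin = max(rel),
       mean_rel_dev_alpha_vs_slin = mean(rel),
       times = sc$grid$times, alpha_hat = est$alpha_s[, 1],
       a = ec$a[, trait_index], truth_lin = truth_lin)
}

#' Static vs dynamic estimator error across a noise grid
#'
#' For each cell of a population-size x noise grid, simulates replicate
#' populations, scores the static (per-time regression) and dynamic
#' (Kalman-filtered) average-effect estimates against the linear
#' sensitivity truth, and summarises the paired comparison.
#'
#' @param seed integer seed.
#' @param M_values population sizes.
#' @param meas_values,dev_values relative measurement / developmental noise
#'   levels.
#' @param n_replicates replicates per cell.
#' @param trait_index trait analysed.
#' @return List with `cells` (data.frame: `M`, `meas`, `dev`,
#'   `err_static`, `err_dynamic`, `n_dynamic_better`, `n_replicates`) and
#'   `detail` (per-cell matrices of paired per-replicate errors).
#' @export
driver_estimator_grid <- function(seed = 1, M_values = c(64, 512),
                                  meas_values = c(0.01, 0.08),
                                  dev_values = c(0.01, 0.20),
                                  n_replicates = 100, trait_index = 1) {
  cells <- expand.grid(M = M_values, meas = meas_values, dev = dev_values)
  detail <- vector("list", nrow(cells))
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    sc <- scenario_noise_grid(M = cell$M, dev_sd_rel = cell$dev,
                              meas_sd_rel = cell$meas,
                              n_replicates = n_replicates,
                              seed = seed + ci)
    errs <- vapply(sc$replicates, function(rep) {
      st <- static_average_effects(rep$series, trait_index = trait_index)
      dy <- kalman_average_effects(st)
      truth <- rep$truth[, trait_index, ]
      c(static = relative_error(st$alpha_s, truth)$mean,
        dynamic = relative_error(dy$alpha_d, truth)$mean)
    }, numeric(2))
    detail[[ci]] <<- t(errs)
    c(err_static = mean(errs["static", ]),
      err_dynamic = mean(errs["dynamic", ]),
      n_dynamic_better = sum(errs["dynamic", ] < errs["static", ]))
  })
  cells <- cbind(cells, do.call(rbind, res))
  cells$n_replicates <- n_replicates
  list(cells = cells, detail = detail)
}

#' Sensitivity-vector alignment through development
#'
#' Variational sensitivities of the environmentally extended toggle switch
#' and the pairwise angles between them over developmental time.
#'
#' @param t_end end of development.
#' @param convention angle convention (see [vec_angle()]).
#' @return List with the `sens`itivity set, the `angles` report, and the
#'   final-time angles `angle_12`, `angle_13`, `angle_23` (degrees).
#' @export
driver_sensitivity_angles <- function(t_end = 50,
                                      convention = "directed") {
  system <- toggle_switch(env = TRUE)
  grid <- time_grid(0, t_end, 1)
  sens <- sensitivities_variational(system, c(0, 0), c(0, 0, 0), grid)
  ang <- angle_report(sens, convention = convention)
  at_end <- ang[ang$time == t_end, ]
  get <- function(i, j) at_end$angle_deg[at_end$param_i == i &
                                           at_end$param_j == j]
  list(sens = sens, angles = ang,
       angle_12 = get(1, 2), angle_13 = get(1, 3), angle_23 = get(2, 3))
}

#' G-P proportionality across minor allele frequencies
#'
#' Builds the analytic G and P = G + E matrices at the final developmental
#' time for architectures drawn at several minor allele frequencies of the
#' second regulatory parameter's loci, and reports the Gmax-Pmax angle.
#'
#' @param seed integer seed.
#' @param mafs minor allele frequencies to compare.
#' @param n_seeds architecture draws per frequency.
#' @param t developmental time of evaluation.
#' @param ... passed to [scenario_maf_alignment()].
#' @return List with `angles` (data.frame `maf`, `seed`, `angle_deg`) and
#'   `median_by_maf`.
#' @export
driver_gp_proportionality <- function(seed = 1,
                                      mafs = c(0.001, 0.016, 0.5),
                                      n_seeds = 10, t = 50, ...) {
  rows <- list()
  sens <- NULL
  for (maf in mafs) {
    for (s in seq_len(n_seeds)) {
      sc <- scenario_maf_alignment(maf, seed = seed * 1000 + s,
                                   simulate = FALSE, t_end = t, ...)
      if (is.null(sens)) sens <- sc$sens
      G <- build_G(sc$sens, sc$loci, t)
      E <- build_E(sc$sens, sc$env, t)
      P <- build_P(G, E)
      rows[[length(rows) + 1]] <-
        data.frame(maf = maf, seed = s,
                   angle_deg = gmax_pmax_angle(G$G, P)$angle_deg)
    }
  }
  angles <- do.call(rbind, rows)
  med <- stats::aggregate(angle_deg ~ maf, angles, stats::median)
  list(angles = angles, median_by_maf = med, sens = sens)
}

#' Selection response vs breeder's-equation predictions
#'
#' Simulates one generation of truncation selection at each minor allele
#' frequency, repeatedly over seeds, and compares the angle between the
#' realized change and the prediction based on the true G against the
#' angle based on P (which collapses to the selection differential).
#'
#' @param seed integer base seed.
#' @param mafs minor allele frequencies.
#' @param n_seeds replicate runs per frequency.
#' @param M population size.
#' @param t_end end of development.
#' @return List with `runs` (data.frame: `maf`, `seed`, `angle_G_obs`,
#'   `angle_P_obs`) and `summary` (per-maf medians and the fraction of
#'   runs where the G-based prediction is closer to the observed change).
#' @export
driver_selection_response <- function(seed = 1, mafs = c(0.001, 0.5),
                                      n_seeds = 20, M = 2000,
                                      t_end = 50) {
  rows <- list()
  for (maf in mafs) {
    for (s in seq_len(n_seeds)) {
      run_seed <- seed * 10000 + s
      sc <- scenario_maf_alignment(maf, seed = run_seed, M = M,
                                   t_end = t_end)
      cfg <- selection_config(seed = run_seed + 1)
      br <- select_and_breed(sc$series, cfg, sc$system, sc$x0, sc$grid,
                             env = sc$env, lambda_ref = sc$lambda_ref)
      G <- build_G(sc$sens, sc$loci, t_end)$G
      Tn <- length(sc$series$times)
      P_emp <- stats::cov(sc$series$true_states[, Tn, ])
      rep <- response_report(br, G, P_emp)
      rows[[length(rows) + 1]] <-
        data.frame(maf = maf, seed = s,
                   angle_G_obs = rep$angle_G_obs,
                   angle_P_obs = rep$angle_P_obs)
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(runs, runs$maf), function(d) {
    data.frame(maf = d$maf[1],
               median_angle_G = stats::median(d$angle_G_obs),
               median_angle_P = stats::median(d$angle_P_obs),
               frac_G_better = mean(d$angle_G_obs < d$angle_P_obs),
               n = nrow(d))
  }))
  list(runs = runs, summary = summary)
}

#' Random-angle null distribution summary
#'
#' @param seed integer seed.
#' @param dim trait-space dimension.
#' @param n_samples number of angle draws.
#' @return List with `mean_angle_deg`, `ks_distance` (empirical CDF vs the
#'   closed-form \eqn{\sin^{d-2}} law) and the null object.
#' @export
driver_random_angle_null <- function(seed = 1, dim = 4, n_samples = 1e5) {
  null <- random_angle_null(dim, n_samples, seed = seed)
  x <- sort(null$angles_deg)
  Fx <- null$cdf(x)
  n <- length(x)
  ks <- max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
  list(mean_angle_deg = mean(null$angles_deg), ks_distance = ks,
       null = null)
}

#' Monte-Carlo validation of the environmental covariance
#'
#' Switches genetics off (all allelic effects zero), draws the
#' environmental parameter many times, develops the population, and
#' compares the empirical covariance of final phenotypes with the
#' first-order sensitivity-based E-matrix.
#'
#' @param seed integer seed.
#' @param n_draws number of environmental draws.
#' @param env_sd SD of the environmental parameter.
#' @param t_end end of development.
#' @return List with `frobenius_rel` (relative Frobenius distance),
#'   `E_analytic`, `E_empirical`.
#' @export
driver_mc_E_check <- function(seed = 1, n_draws = 1e4, env_sd = 1.5e-3,
                              t_end = 50) {
  system <- toggle_switch(env = TRUE)
  grid <- time_grid(0, t_end, 1)
  lambda_ref <- c(0, 0, 0)
  loci <- loci_table(target_param = 1, gamma = 0, freq_B = 0.5)
  geno <- genotype_matrix(codes = matrix(0, n_draws, 1))
  env <- env_spec(3, env_sd)
  set.seed(seed)
  series <- simulate_population(system, c(0, 0), grid, geno, loci,
                                env = env, lambda_ref = lambda_ref,
                                h_int = 0.05)
  Tn <- length(grid$times)
  E_emp <- stats::cov(series$true_states[, Tn, ])
  sens <- sensitivities_variational(system, c(0, 0), lambda_ref, grid)
  E_an <- build_E(sens, env, t_end)$E
  list(frobenius_rel = norm(E_emp - E_an, "F") / norm(E_an, "F"),
       E_analytic = E_an, E_empirical = E_emp)
}

# ---- pipeline runner -------------------------------------------------------

#' Validate a pipeline configuration
#'
#' @param config named list; must contain `scenario` (one of
#'   `"single_locus"`, `"maf_alignment"`, `"noise_grid"`) and `seed`
#'   (integer).  Scenario-specific fields are optional and have defaults.
#' @return The config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  required <- c("scenario", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  scenarios <- c("single_locus", "maf_alignment", "noise_grid")
  if (!config$scenario %in% scenarios) {
    stop("unknown scenario '", config$scenario, "'; expected one of ",
         paste(scenarios, collapse = ", "))
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    stop("config field 'seed' must be a single integer")
  }
  invisible(config)
}

#' Run a pipeline stage from a configuration
#'
#' Executes one scenario end to end and writes its numeric artifacts
#' (tidy CSVs and a summary JSON) plus a run log into `out_dir`.  All
#' randomness flows from `config$seed`, so re-running the same
#' configuration reproduces every data artifact byte-for-byte (the log
#' carries timestamps and may differ).  Artifacts are staged in a
#' temporary directory and moved on success, so a failed run leaves no
#' partial outputs.
#'
#' @param config named list (see [validate_config()]) or path to a JSON
#'   file containing one.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  validate_config(config)
  t_start <- Sys.time()
  stage <- file.path(tempfile("devqg_stage"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                     file.path(stage, name), row.names = FALSE,
                     quote = FALSE)
  }
  wjson <- function(x, name) {
    jsonlite::write_json(x, file.path(stage, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  seed <- as.integer(config$seed)
  if (config$scenario == "single_locus") {
    dr <- driver_single_locus(seed = seed,
                              gamma = config$gamma %||% 1e-2)
    sc <- scenario_single_locus(seed = seed,
                                gamma = config$gamma %||% 1e-2)
    st <- static_average_effects(sc$series)
    dy <- kalman_average_effects(st)
    wcsv(phenotype_to_df(sc$series), "population.csv")
    wcsv(sensitivity_to_df(sc$sens), "sensitivities.csv")
    wcsv(data.frame(time = st$times, locus = 1,
                    alpha_static = st$alpha_s[, 1], se = st$se[, 1],
                    alpha_dynamic = dy$alpha_d[, 1],
                    var_dynamic = dy$var_d[, 1]),
         "estimates.csv")
    wjson(list(max_abs_dev_alpha_vs_a = dr$max_abs_dev_alpha_vs_a,
               max_rel_dev_alpha_vs_slin = dr$max_rel_dev_alpha_vs_slin),
          "summary.json")
  } else if (config$scenario == "maf_alignment") {
    sc <- scenario_maf_alignment(config$maf %||% 0.5, seed = seed,
                                 M = config$M %||% 500)
    t_end <- sc$grid$t_end
    G <- build_G(sc$sens, sc$loci, t_end)
    E <- build_E(sc$sens, sc$env, t_end)
    P <- build_P(G, E)
    rep <- gmax_pmax_angle(G$G, P)
    wcsv(phenotype_to_df(sc$series), "population.csv")
    wcsv(sensitivity_to_df(sc$sens), "sensitivities.csv")
    wjson(list(time = t_end, maf = config$maf %||% 0.5,
               angle_gmax_pmax_deg = rep$angle_deg,
               G = G$G, E = E$E, P = P,
               eigenvalues_G = rep$eig_G, eigenvalues_P = rep$eig_P),
          "covariances.json")
  } else if (config$scenario == "noise_grid") {
    dr <- driver_estimator_grid(
      seed = seed,
      M_values = config$M_values %||% 64,
      meas_values = config$meas_values %||% 0.08,
      dev_values = config$dev_values %||% 0.01,
      n_replicates = config$n_replicates %||% 5)
    wcsv(dr$cells, "errors.csv")
    wjson(list(cells = dr$cells), "summary.json")
  }
  wjson(config, "config.json")
  log_lines <- c(paste("devqg", as.character(utils::packageVersion("devqg"))),
                 paste("scenario:", config$scenario),
                 paste("seed:", seed),
                 paste("started:", format(t_start)),
                 paste("elapsed_s:",
                       round(as.numeric(difftime(Sys.time(), t_start,
                                                 units = "secs")), 3)))
  writeLines(log_lines, file.path(stage, "log.txt"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(stage)
  ok <- file.copy(file.path(stage, files), file.path(out_dir, files),
                  overwrite = TRUE)
  if (!all(ok)) stop("failed to move artifacts to ", out_dir)
  invisible(file.path(out_dir, files))
}
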