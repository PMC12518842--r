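# End-to-end orchestration: configuration validation and the synthetic
# "measure -> model -> fit -> decompose" pipeline with per-stage artifacts.

.default_config <- function() {
  list(
    output_dir = tempfile("igdyn_run_"),
    seed = 1L,
    model = list(source = "synthetic", fragment_radius = 4.2,
                 fragment_center_distance = 4.6, beads_per_fragment = 30L,
                 pdb_path = NULL, chain_map = NULL),
    conditions = list(temperature_C = 25, solvent = "D2O"),
    hydro = list(bead_radius = 1.2),
    saxs = list(concentrations = c(5, 10, 25), M_w = 148, noise_frac = 0.01,
                Q = list(min = 0.05, max = 2.5, n = 60),
                radius = 5.4, charge = 10, ionic_strength = 50),
    refine = list(lower = c(in_plane.Fab_l = -0.6, radial.Fab_l = -1.5),
                  upper = c(in_plane.Fab_l = 0.6, radial.Fab_l = 1.5),
                  maxiter_de = 12L),
    nse = list(Q = seq(0.2, 1.8, length.out = 10), t_max = 150, n_t = 20,
               u_f = 1.0, lambda = 40, noise_frac = 0.02,
               concentration = 50),
    decompose = list(lambda_fixed = 200, f_c = 0.75, f_r = 1.0,
                     u_m = 1.0, u_r = 0.8),
    cumulant_t_max = 20
  )
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults and rejects unknown keys.  The configuration can be a
#' nested list or a path to a YAML/JSON file.
#'
#' @param config List or file path; `NULL` gives the defaults.
#' @return Completed configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- .default_config()
  if (is.null(config)) config <- list()
  merge_lists <- function(d, u, path = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]) && !is.null(names(d[[k]])))
        merge_lists(d[[k]], u[[k]], paste0(path, k, ".")) else u[[k]]
    }
    d
  }
  out <- merge_lists(def, config)
  stopifnot(out$seed == as.integer(out$seed))
  class(out) <- c("pipeline_config", "list")
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the package's stages end to end with known ground truth: build the
#' coarse-grained model; generate a SAXS concentration series and extrapolate
#' the form factor; recover the configuration by refinement; compute the
#' rigid-body diffusion tensor; assemble the slow diffusion coefficient from
#' translational (H/S-corrected), rotational and internal-mode components;
#' generate and fit NSE spectra (shared u_f, lambda, per-Q D_slow); run the
#' cumulant analysis; decompose D_slow; convert the fast relaxation into
#' Ornstein-Uhlenbeck force and friction.  Per-stage artifacts (CSV/JSON) are
#' written under `config$output_dir`; reruns with the same configuration and
#' seed are identical.
#'
#' @param config A [pipeline_config()], nested list, or file path.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  env <- environment_conditions(cfg$conditions$temperature_C + 273.15,
                                solvent = cfg$conditions$solvent)

  model <- stage("model", {
    if (cfg$model$source == "synthetic") {
      build_synthetic_ymodel(cfg$model$fragment_radius,
                             cfg$model$fragment_center_distance,
                             cfg$model$beads_per_fragment, seed = cfg$seed)
    } else {
      load_pdb_coarse_grain(cfg$model$pdb_path,
                            unlist(cfg$model$chain_map))
    }
  })
  write_bead_model(model, file.path(cfg$output_dir, "bead_model.csv"))
  report$model <- list(n_beads = nrow(model$positions),
                       R_g = radius_of_gyration(model),
                       bounding_radius = bounding_radius(model))

  hydro <- stage("hydro", rpy_rigid_body_tensor(model, cfg$hydro$bead_radius, env))
  R_h <- stokes_einstein_radius(hydro$D_t, env)
  report$hydro <- list(D_t = hydro$D_t, D_r0 = hydro$D_r0, R_h = R_h,
                       tau_r0_ns = 1 / (6 * hydro$D_r0))
  jsonlite::write_json(list(diffusion_matrix = hydro$diffusion_matrix,
                            D_t = hydro$D_t, D_r0 = hydro$D_r0),
                       file.path(cfg$output_dir, "hydro.json"),
                       digits = NA, matrix = "rowmajor")

  saxs <- stage("saxs", {
    Qg <- seq(cfg$saxs$Q$min, cfg$saxs$Q$max, length.out = cfg$saxs$Q$n)
    sqp <- lapply(cfg$saxs$concentrations, function(cc)
      sq_params_from_concentration(cc, cfg$saxs$M_w, cfg$saxs$radius,
                                   model = "RMSA", charge = cfg$saxs$charge,
                                   ionic_strength = cfg$saxs$ionic_strength))
    gen_saxs_series(model, sqp, cfg$saxs$concentrations, Qg,
                    M_w = cfg$saxs$M_w, noise_frac = cfg$saxs$noise_frac,
                    seed = cfg$seed + 1L)
  })
  for (i in seq_along(saxs$curves))
    write_curve(saxs$curves[[i]],
                file.path(cfg$output_dir,
                          sprintf("saxs_c%03d.dat", round(cfg$saxs$concentrations[i]))))
  write_truth(saxs$truth, file.path(cfg$output_dir, "saxs_truth.json"))

  Pest <- stage("form_factor", extrapolate_form_factor(saxs$curves,
                                                       M_w = cfg$saxs$M_w))
  write_curve(Pest, file.path(cfg$output_dir, "form_factor.dat"))
  report$saxs <- list(P0 = Pest$I[1],
                      P0_true = saxs$truth$P$I[1])

  refine <- stage("refine", {
    # perturb the model, then recover the configuration against the
    # extrapolated form factor of the unperturbed truth
    truth_params <- configuration_params(in_plane = c(Fab_l = 0.25),
                                         radial = c(Fab_l = 0.6))
    perturbed <- apply_configuration(model, truth_params)
    r <- refine_configuration(perturbed, Pest,
                              lower = unlist(cfg$refine$lower),
                              upper = unlist(cfg$refine$upper),
                              seed = cfg$seed + 2L,
                              maxiter_de = cfg$refine$maxiter_de)
    list(result = r, truth = truth_params)
  })
  report$refine <- list(chisq_red = refine$result$fit$chisq_red,
                        par = as.list(refine$result$fit$par),
                        R_g_refined = radius_of_gyration(refine$result$model),
                        R_g_truth = radius_of_gyration(model))

  nse <- stage("nse", {
    Qn <- cfg$nse$Q
    Qgrid <- sort(unique(c(Qn, seq(0.1, 2.5, length.out = 40))))
    attack <- mode_set(model, lapply(.fragments(model), function(f)
      make_displacement_mode(model, "attack", f)), Qgrid,
      amplitude = cfg$nse$u_f, lambda = cfg$nse$lambda, n_orientations = 301L)
    search <- mode_set(model, c(
      lapply(.fragments(model), function(f)
        make_displacement_mode(model, "search_in_plane", f)),
      lapply(.fragments(model), function(f)
        make_displacement_mode(model, "search_out_of_plane", f))), Qgrid,
      amplitude = cfg$decompose$u_m, lambda = cfg$decompose$lambda_fixed,
      n_orientations = 301L)
    fragrot <- mode_set(model, lapply(.fragments(model), function(f)
      make_displacement_mode(model, "fragment_rotation", f)), Qgrid,
      amplitude = cfg$decompose$u_r, lambda = cfg$decompose$lambda_fixed,
      n_orientations = 301L)
    n <- .number_density(cfg$nse$concentration, cfg$saxs$M_w)
    Squot <- structure_factor(sq_params(model = "hard_sphere_PY",
                                        radius = cfg$saxs$radius,
                                        volume_fraction = n * 4 * pi * cfg$saxs$radius^3 / 3),
                              Qgrid)
    H <- delta_gamma_H(Squot, cfg$decompose$f_c * R_h, n, Qn)
    Sn <- stats::approx(Squot$Q, Squot$I, xout = Qn, rule = 2)$y
    DQ <- rigid_body_DQ(model, hydro, Qn)
    dmv <- function(ms, u) {
      r <- stats::approx(ms$Q, ms$P_alpha_sum / ms$P, xout = Qn, rule = 2)$y
      u^2 * r / (1 + u^2 * r) / (cfg$decompose$lambda_fixed * Qn^2)
    }
    D_slow_true <- hydro$D_t * H$H / Sn +
      cfg$decompose$f_r * rotational_hindrance(attr(H, "Phi_HI")) * DQ$Dr +
      dmv(search, cfg$decompose$u_m) + dmv(fragrot, cfg$decompose$u_r)
    gen <- gen_nse(attack, cfg$nse$u_f, cfg$nse$lambda, D_slow_true, Qn,
                   t_grids = c(0, 10^seq(log10(0.5), log10(cfg$nse$t_max),
                                         length.out = cfg$nse$n_t - 1)),
                   noise_frac = cfg$nse$noise_frac, seed = cfg$seed + 3L)
    list(gen = gen, attack = attack, search = search, fragrot = fragrot,
         S = Squot, n = n, D_slow_true = D_slow_true)
  })
  write_nse(nse$gen$spectrum, file.path(cfg$output_dir, "nse.csv"))
  write_truth(nse$gen$truth, file.path(cfg$output_dir, "nse_truth.json"))

  fitc <- stage("fit_nse", fit_composite(nse$gen$spectrum, nse$attack))
  report$nse_fit <- list(u_f = fitc$u_f, u_f_err = fitc$u_f_err,
                         lambda = fitc$lambda, lambda_err = fitc$lambda_err,
                         u_f_true = cfg$nse$u_f, lambda_true = cfg$nse$lambda,
                         D_slow = fitc$D_slow$D_slow,
                         D_slow_true = nse$D_slow_true)

  cum <- stage("cumulant", cumulant_fit(nse$gen$spectrum,
                                        t_max = cfg$cumulant_t_max))
  utils::write.csv(cum, file.path(cfg$output_dir, "cumulant.csv"),
                   row.names = FALSE)
  report$cumulant <- list(Q = cum$Q, D_cum = cum$D_cum)

  dec <- stage("decompose", decompose_slow(
    data.frame(Q = fitc$D_slow$Q, D_slow = fitc$D_slow$D_slow,
               sigma = pmax(fitc$D_slow$sigma, 1e-6)),
    hydro, model, nse$S, nse$search, nse$fragrot, nse$n, R_h,
    lambda_fixed = cfg$decompose$lambda_fixed))
  utils::write.csv(as.data.frame(dec),
                   file.path(cfg$output_dir, "decomposition.csv"),
                   row.names = FALSE)
  fdec <- attr(dec, "fit")
  report$decompose <- list(par = as.list(fdec$par),
                           errors = as.list(fdec$errors),
                           truth = cfg$decompose[c("f_c", "f_r", "u_m", "u_r")],
                           Phi_HI = attr(dec, "Phi_HI"))

  report$ou <- stage("ou", {
    kT <- kT_molar(env$temperature)
    k_f <- kT / fitc$u_f^2
    xi <- k_f * fitc$lambda
    list(k_f = k_f, xi = xi,
         k_f_pN_nm = force_unit_convert(k_f),
         entropic_reference = c(N8 = entropic_spring_constant(8),
                                N18 = entropic_spring_constant(18)))
  })

  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
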