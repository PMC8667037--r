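#' Define one experimental condition
#'
#' A condition pairs one or more connector species (a mixture contributes
#' the sum of its species' link rates) with a rate model and optional
#' simulator overrides.
#'
#' @param label Unique condition label.
#' @param connectors A [connector_spec()] or list of them (a mixture).
#' @param model A [rate_model()].
#' @param docking A [docking_spec()].
#' @param sim_overrides Named list of [sim_config()] fields overriding the
#'   experiment defaults for this condition.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label, connectors, model = rate_model(),
                           docking = docking_spec(), sim_overrides = list()) {
  if (inherits(connectors, "connector_spec")) connectors <- list(connectors)
  stopifnot(all(vapply(connectors, inherits, logical(1L), "connector_spec")))
  structure(
    list(label = label, connectors = connectors, model = model,
         docking = docking, sim_overrides = sim_overrides),
    class = "condition_spec")
}

#' Total per-edge-pair link rate of a condition
#'
#' Sum of [link_rate_from_connector()] over the condition's connector
#' species.
#'
#' @param condition A [condition_spec()].
#' @return Link rate in per-second.
#' @export
condition_link_rate <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  sum(vapply(condition$connectors, function(cn)
    link_rate_from_connector(condition$model, cn, condition$docking),
    numeric(1L)))
}

#' The benchmarked connector panel
#'
#' The full set of connector designs compared experimentally, mapped onto
#' [condition_spec()]s: scaffold connectors with and without a short
#' flexible linker (250 nM, hairpin-penalized), oligo-C-spacer repeat
#' connectors with oligo-T sticker lengths 6-9 nt (250 nM; the 9-nt sticker
#' offers 3 reading frames against the 7-nt oligo-A docking extension),
#' all-T connectors of total lengths 14, 20, 40, 60 and 80 nt (250 nM), and
#' the T_N mixture of all five lengths at 50 nM each.
#'
#' @param base_on_rate Base hybridization on-rate per matched register,
#'   per-molar per-second.
#' @param scaffold_accessibility Hairpin-accessibility factor applied to
#'   scaffold connectors (their sequence can fold back on itself; repeat
#'   connectors get 1).
#' @param valence_multiplier Multi-site valence factor shared by all
#'   conditions (four docking extensions per edge).
#' @param docking A [docking_spec()].
#' @return Named list of `condition_spec`s.
#' @export
paper_condition_table <- function(base_on_rate = 1e6,
                                  scaffold_accessibility = 0.2,
                                  valence_multiplier = 4,
                                  docking = docking_spec()) {
  repeat_model <- rate_model(base_on_rate, 1, valence_multiplier)
  scaffold_model <- rate_model(base_on_rate, scaffold_accessibility,
                               valence_multiplier)
  conds <- list()
  conds$scaffold <- condition_spec(
    "scaffold",
    connector_spec("scaffold", total_length = 32L, sticker_length = 16L,
                   concentration = 250, label = "scaffold"),
    model = scaffold_model, docking = docking,
    sim_overrides = list(orientation_rule = "parallel_only"))
  conds$`scaffold+linker` <- condition_spec(
    "scaffold+linker",
    connector_spec("scaffold", total_length = 40L, sticker_length = 16L,
                   flexible_linker = TRUE, concentration = 250,
                   label = "scaffold+linker"),
    model = scaffold_model, docking = docking,
    sim_overrides = list(orientation_rule = "parallel_only"))
  for (s in 6:9) {
    lab <- sprintf("sticker%dnt", s)
    conds[[lab]] <- condition_spec(
      lab,
      connector_spec("repeat", total_length = 40L, sticker_length = s,
                     spacer_length = 40L - 2L * s, concentration = 250,
                     label = lab),
      model = repeat_model, docking = docking)
  }
  for (tl in c(14L, 20L, 40L, 60L, 80L)) {
    lab <- sprintf("T%d", tl)
    conds[[lab]] <- condition_spec(
      lab,
      connector_spec("repeat", total_length = tl, concentration = 250,
                     label = lab),
      model = repeat_model, docking = docking)
  }
  conds$TN_mix <- condition_spec(
    "TN_mix",
    lapply(c(14L, 20L, 40L, 60L, 80L), function(tl)
      connector_spec("repeat", total_length = tl, concentration = 50,
                     label = sprintf("T%d", tl))),
    model = repeat_model, docking = docking)
  conds
}

#' Experiment configuration
#'
#' @param conditions List of [condition_spec()]s with unique labels.
#' @param sim_defaults A [sim_config()] providing shared simulator settings
#'   (its `link_rate` is replaced per condition).
#' @param optics,camera Imaging configuration.
#' @param brightness Fluorophores per monomer.
#' @param n_replicates Replicates per condition.
#' @param master_seed Integer master seed; all per-replicate seeds derive
#'   from it and it is recorded in every output.
#' @param output_dir Directory for artifacts (`NULL` keeps everything in
#'   memory).
#' @param drop_fraction Decay-detection threshold for
#'   [fit_assembly_timescale()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(conditions, sim_defaults, optics = optics_config(),
                              camera = camera_config(), brightness = 5,
                              n_replicates = 1L, master_seed = 1L,
                              output_dir = NULL, drop_fraction = 0.5) {
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  labels <- vapply(conditions, function(x) x$label, character(1L))
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  if (n_replicates < 1L) stop("need at least one replicate")
  structure(
    list(conditions = conditions, sim_defaults = sim_defaults,
         optics = optics, camera = camera, brightness = brightness,
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed), output_dir = output_dir,
         drop_fraction = drop_fraction),
    class = "experiment_config")
}

# Merge per-condition overrides into the default sim config.
merged_sim_config <- function(defaults, overrides, link_rate, seed) {
  args <- unclass(defaults)
  args[names(overrides)] <- overrides
  args$link_rate <- link_rate
  args$rng_seed <- seed
  do.call(sim_config, args)
}

#' Run a full in-silico cross-linking experiment
#'
#' For every condition x replicate: derive the link rate from the connector
#' design, simulate assembly, render every scheduled observation window,
#' compute the correlation time course and fit the assembly timescale. When
#' `output_dir` is set, writes per-window TIFF stacks (with JSON metadata
#' sidecars), a per-replicate CSV of the correlation time course, a JSON fit
#' report, and a `summary.csv` across conditions; all outputs carry the
#' master seed. A failing replicate is recorded and the experiment
#' continues. Byte-identical outputs are produced for identical master
#' seeds.
#'
#' @param config An [experiment_config()].
#' @param write_stacks Write rendered TIFF stacks (they dominate disk use;
#'   time courses and reports are always written when `output_dir` is set).
#' @return List of class `experiment_report`: per-condition
#'   `condition_report`s (label, per-replicate fits and time courses,
#'   fitted/acquired counts, mean and s.d. of `t_half` over fitted
#'   replicates) plus a `summary` data frame.
#' @export
run_experiment <- function(config, write_stacks = !is.null(config$output_dir)) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  reports <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    link_rate <- condition_link_rate(cond)
    fits <- vector("list", config$n_replicates)
    tcs <- vector("list", config$n_replicates)
    errors <- character(config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      seed <- derive_seed(config$master_seed, ci, r)
      res <- tryCatch({
        scfg <- merged_sim_config(config$sim_defaults, cond$sim_overrides,
                                  link_rate, seed)
        traj <- run_assembly(scfg)
        stacks <- lapply(seq_along(traj$windows), function(wi) {
          stk <- render_stack(traj$windows[[wi]], config$optics,
                              config$camera, brightness = config$brightness,
                              seed = derive_seed(seed, 1000L + wi))
          if (write_stacks && !is.null(out_dir))
            write_stack(stk, file.path(out_dir,
              sprintf("%s_rep%02d_win%02d.tif", cond$label, r, wi)))
          stk
        })
        tc <- correlation_timecourse(stacks, condition = cond$label)
        # an unfittable time course (e.g. too few windows) is a per-replicate
        # "no fit", not an experiment failure
        fit <- tryCatch(fit_assembly_timescale(tc, config$drop_fraction),
                        error = function(e) structure(
                          list(C_peak = NA_real_, C_base = NA_real_,
                               t_half = NA_real_, width = NA_real_,
                               fitted = FALSE, residual_norm = NA_real_,
                               diagnostic = conditionMessage(e)),
                          class = "kinetics_fit"))
        list(tc = tc, fit = fit)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[r] <- conditionMessage(res)
        fits[[r]] <- NULL
      } else {
        tcs[[r]] <- res$tc
        fits[[r]] <- res$fit
        if (!is.null(out_dir)) {
          tc_path <- file.path(out_dir,
            sprintf("%s_rep%02d_timecourse.csv", cond$label, r))
          utils::write.csv(as.data.frame(res$tc), tc_path, row.names = FALSE)
          fit_path <- file.path(out_dir,
            sprintf("%s_rep%02d_fit.json", cond$label, r))
          jsonlite::write_json(
            c(unclass(res$fit),
              list(condition = cond$label, replicate = r,
                   master_seed = config$master_seed, seed = seed,
                   link_rate = link_rate)),
            fit_path, auto_unbox = TRUE, digits = NA, null = "null")
        }
      }
    }
    fitted_flags <- vapply(fits, function(f)
      !is.null(f) && isTRUE(f$fitted), logical(1L))
    t_halves <- vapply(fits[fitted_flags], `[[`, numeric(1L), "t_half")
    reports[[cond$label]] <- structure(
      list(label = cond$label, link_rate = link_rate, fits = fits,
           timecourses = tcs, errors = errors,
           fitted_count = sum(fitted_flags),
           acquired_count = config$n_replicates,
           t_half_mean = if (length(t_halves)) mean(t_halves) else NA_real_,
           t_half_sd = if (length(t_halves) > 1L) stats::sd(t_halves)
                       else NA_real_),
      class = "condition_report")
  }
  summary <- do.call(rbind, lapply(reports, function(rep) {
    data.frame(condition = rep$label, link_rate = rep$link_rate,
               fitted = rep$fitted_count, acquired = rep$acquired_count,
               t_half_mean = rep$t_half_mean, t_half_sd = rep$t_half_sd,
               master_seed = config$master_seed)
  }))
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  structure(list(conditions = reports, summary = summary, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %s: %d/%d fitted, t_half = %.3g +- %.3g s\n",
              x$label, x$fitted_count, x$acquired_count,
              x$t_half_mean, x$t_half_sd))
  invisible(x)
}

#' Arrow-shaped docking-site layout
#'
#' The 36-site arrow pattern used on the origami monomer so that
#' super-resolution images reveal each monomer's orientation within a
#' superstructure. Coordinates are synthetic: an arrowhead and a filled
#' shaft laid out with exact bilateral symmetry about the arrow axis
#' (y = 0), inside a 100 x 70 nm monomer footprint. Intended for renderer
#' fixtures and documentation figures.
#'
#' @return Data frame of 36 rows with columns `x`, `y` (nm); the footprint
#'   is stored in the `footprint` attribute (`c(xmax, ymax_halfwidth)`).
#' @export
arrow_fixture <- function() {
  shaft_x <- seq(0, 60, by = 10)
  shaft <- expand.grid(x = shaft_x, y = c(-11, 0, 11))
  head_cols <- list(
    list(x = 66, y = c(-22, -11, 0, 11, 22)),
    list(x = 74, y = c(-16.5, -5.5, 5.5, 16.5)),
    list(x = 82, y = c(-11, 0, 11)),
    list(x = 90, y = c(-5.5, 5.5)),
    list(x = 98, y = 0))
  head <- do.call(rbind, lapply(head_cols, function(cl)
    data.frame(x = cl$x, y = cl$y)))
  out <- rbind(shaft[, c("x", "y")], head)
  rownames(out) <- NULL
  attr(out, "footprint") <- c(100, 35)
  out
}
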