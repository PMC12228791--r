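## End-to-end orchestration: a structured config drives the stages, every
## report carries the config hash and root seed, and a manifest lists all
## outputs with checksums so a rerun can be verified byte for byte.

#' Build and validate a run configuration
#'
#' @param config a named list or a path to a JSON config file. Recognised
#'   fields: \code{stages} (character vector), \code{seed} (integer root
#'   seed), \code{output_dir}, \code{lattice} (list of
#'   [helical_lattice()] arguments), \code{input_star} (path, required by
#'   table stages unless \code{simulate} runs first), \code{simulate}
#'   (list of [filament_sim_spec()] arguments minus the lattice),
#'   \code{smooth} (window, outlier_threshold), \code{partners},
#'   \code{focus_offset}, \code{occupancy_labels}, \code{plan} (data.frame
#'   coercible [protocol_plan()] levels; default the three-level adaptive
#'   seeding plan).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(stages = character(0), seed = 1L, output_dir = "mtmotor_out",
                   lattice = list(n_pf = 13L), smooth = list(),
                   partners = 7, focus_offset = c(0, 0, 0))
  config <- utils::modifyList(defaults, config)
  known <- c("simulate", "vote", "smooth", "phi_median", "average", "seam",
             "seam_assign", "expand", "subparticles", "occupancy", "ledger")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (!is.null(config$input_star) && !file.exists(config$input_star) &&
      !"simulate" %in% config$stages)
    stop("input_star does not exist: ", config$input_star)
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; identical configs hash
#' identically across sessions.
#'
#' @param config a [run_config()] (or any jsonlite-serialisable list).
#' @return character MD5 hex digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$output_dir <- NULL   # hash identifies the analysis, not its location
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.write_report <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

#' Run the pipeline stages declared in a configuration
#'
#' Executes the declared stages in order on a shared filament-table state,
#' writing one JSON report per stage into \code{output_dir} and a final
#' manifest listing every output with its MD5 checksum, the config hash and
#' the root seed. Identical configs reproduce identical manifests; all
#' randomness flows from the root seed. A stage failure aborts with an
#' error naming the stage.
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)
  lattice <- do.call(helical_lattice, config$lattice)
  state <- NULL     # current filament table
  outputs <- character(0)
  stamp <- function(x) c(list(config_hash = chash, seed = config$seed), x)
  need_table <- function(stage) {
    if (is.null(state)) {
      if (is.null(config$input_star))
        stop("stage '", stage, "' needs a table: provide input_star or a ",
             "preceding simulate stage")
      state <<- read_filament_star(config$input_star)
    }
    state
  }
  out <- function(name) file.path(config$output_dir, name)

  for (stage in config$stages) {
    res <- tryCatch(switch(
      stage,
      simulate = {
        args <- config$simulate
        args$lattice <- lattice
        if (is.null(args$seed)) args$seed <- config$seed
        sim <- make_filament_table(do.call(filament_sim_spec, args))
        state <- sim$table
        paths <- write_filament_sim(sim, out("simulated_particles.star"))
        outputs <- c(outputs, paths)
        .write_report(stamp(list(
          n_rows = nrow(state),
          true_registers = as.list(sim$truth$true_registers))),
          out("simulate.json"))
      },
      vote = {
        v <- modal_class_vote(need_table(stage))
        state <- v$table
        .write_report(stamp(list(assignments = as.list(v$assignments))),
                      out("vote.json"))
      },
      smooth = {
        args <- config$smooth
        state <- smooth_inplane(need_table(stage),
                                window = args$window %||% 5,
                                outlier_threshold = args$outlier_threshold %||% 8)
        .write_report(stamp(list(n_rows = nrow(state))), out("smooth.json"))
      },
      phi_median = {
        state <- assign_phi_median(need_table(stage))
        .write_report(stamp(list(n_rows = nrow(state))), out("phi_median.json"))
      },
      average = {
        state <- segment_average(need_table(stage), partners = config$partners)
        .write_report(stamp(list(n_rows = nrow(state))), out("average.json"))
      },
      seam = {
        hyps <- enumerate_seam_references(lattice)
        .write_report(stamp(list(
          n_hypotheses = length(hyps),
          hypotheses = lapply(hyps, unclass))), out("seam.json"))
      },
      seam_assign = {
        a <- assign_seam_register(need_table(stage), lattice)
        state <- a$table
        .write_report(stamp(list(
          assignments = lapply(a$assignments, unclass))),
          out("seam_assign.json"))
      },
      expand = {
        state <- {
          tb <- need_table(stage)
          expanded <- symmetry_expand(tb, lattice)
          expanded
        }
        .write_report(stamp(list(n_rows = nrow(state))), out("expand.json"))
      },
      subparticles = {
        if (is.null(state)) need_table(stage)
        state <- subparticle_coords(state, as.numeric(config$focus_offset))
        .write_report(stamp(list(n_rows = nrow(state),
                                 focus_offset = config$focus_offset)),
                      out("subparticles.json"))
      },
      occupancy = {
        if (is.null(config$occupancy_labels))
          stop("occupancy stage needs occupancy_labels in the config")
        rep <- occupancy_stats(unlist(config$occupancy_labels))
        .write_report(stamp(list(counts = as.list(rep$counts),
                                 fractions = as.list(rep$fractions),
                                 n = rep$n)), out("occupancy.json"))
      },
      ledger = {
        plan <- if (is.null(config$plan)) adaptive_seeding_plan() else
          protocol_plan(as.data.frame(config$plan))
        led <- sim_time_ledger(plan)
        .write_report(stamp(list(total_us = led$total_us,
                                 per_level = led$per_level)),
                      out("ledger.json"))
      }),
      error = function(e) stop("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    outputs <- c(outputs, res)
  }
  if (!is.null(state) && length(config$stages)) {
    final_star <- out("final_table.star")
    df <- as.data.frame(state)
    idx <- match(names(df), names(.star_map))
    names(df)[!is.na(idx)] <- .star_map[idx[!is.na(idx)]]
    write_star(df, final_star)
    outputs <- c(outputs, final_star)
  }
  outputs <- unique(outputs)
  manifest <- list(config_hash = chash, seed = config$seed,
                   stages = config$stages,
                   files = lapply(outputs, function(p) list(
                     path = p, md5 = unname(tools::md5sum(p)))))
  .write_report(manifest, out("manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
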