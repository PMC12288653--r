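# Serialization (JSON for parameterized objects, CSV for traces), run
# configuration, and the command-line entry point.

ARTIFACT_VERSION <- "1"

#' Save a network, controller, or evolution trace to disk
#'
#' Networks and controllers are written as JSON (matrices row-major, full
#' double precision, fields named as in their constructors, plus `class`
#' and `version` fields); evolution traces are written as CSV with columns
#' `step`, `cost`, `accepted`, `temperature`, `mode_gap`. Round-trips
#' through [load_artifact()] preserve all fields to full precision.
#'
#' @param object a [gene_network()], [pi_controller()], or
#'   [anneal()] trace.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_artifact <- function(object, path) {
  if (inherits(object, "evolution_trace")) {
    utils::write.csv(object$trace, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(object, "gene_network")) {
    list(
      class = "gene_network", version = ARTIFACT_VERSION,
      n_genes = object$n_genes,
      k_mat = as.vector(t(object$k_mat)),  # row-major
      K_mat = as.vector(t(object$K_mat)),
      decay = object$decay, n_wt = object$n_wt
    )
  } else if (inherits(object, "pi_controller")) {
    list(
      class = "pi_controller", version = ARTIFACT_VERSION,
      k_channels = object$k_channels, n_genes = object$n_genes,
      sense_mat = as.vector(t(object$sense_mat)),
      action_mat = as.vector(t(object$action_mat)),
      c_p = object$c_p, c_i = object$c_i
    )
  } else {
    stop("don't know how to serialize objects of class ",
         paste(class(object), collapse = "/"), call. = FALSE)
  }
  # digits = I(17): significant digits, enough for exact double round-trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a network or controller saved by [save_artifact()]
#'
#' Re-validates all invariants on load (positive half-saturation constants,
#' orthonormal sensing rows, ...). A `version` mismatch produces a warning,
#' not a failure; a missing or malformed field is an error naming it.
#'
#' @param path JSON file written by [save_artifact()].
#' @return the restored object.
#' @export
load_artifact <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$class)) stop("corrupt artifact: missing `class` field", call. = FALSE)
  if (!identical(as.character(obj$version), ARTIFACT_VERSION)) {
    warning("artifact version ", obj$version, " differs from current ",
            ARTIFACT_VERSION, call. = FALSE)
  }
  need <- function(field) {
    if (is.null(obj[[field]])) {
      stop("corrupt artifact: missing field `", field, "`", call. = FALSE)
    }
    obj[[field]]
  }
  switch(
    obj$class,
    gene_network = {
      n <- need("n_genes")
      gene_network(
        k_mat = matrix(need("k_mat"), n, n, byrow = TRUE),
        K_mat = matrix(need("K_mat"), n, n, byrow = TRUE),
        decay = need("decay"),
        n_wt = obj$n_wt
      )
    },
    pi_controller = {
      k <- need("k_channels")
      n <- need("n_genes")
      pi_controller(
        sense_mat = matrix(need("sense_mat"), k, n, byrow = TRUE),
        action_mat = matrix(need("action_mat"), n, k, byrow = TRUE),
        c_p = need("c_p"), c_i = need("c_i")
      )
    },
    stop("corrupt artifact: unknown class `", obj$class, "`", call. = FALSE)
  )
}

# ---- run configuration -----------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1L,
    n_genes = 10L,
    k_channels = 1L,
    fitness = list(n_env_samples = 20L, env_sd = 0.1,
                   eval_mode = "linearized", stiffness_norm = "uncontrolled"),
    anneal = list(n_steps = 2000L, T_init = 0.05, T_final = 1e-4,
                  cooling = "geometric", proposal_sd = 0.1,
                  mutate_prob = 0.2, mutate_network = TRUE,
                  mutate_controller = TRUE, k_bounds = c(0.02, 5),
                  K_bounds = c(0.05, 50), global_prob = 0.2),
    mutation = list(magnitude = 0.05, n_mutations = 100L, target = "both"),
    ensemble = list(env_sd = 0.1, n_draws = 200L)
  )
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults)) {
      stop("unknown config key `", full, "`", call. = FALSE)
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]])) {
        stop("config key `", full, "` must be a section", call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$k_channels < 1 || cfg$k_channels > cfg$n_genes) {
    stop("config: need 1 <= k_channels <= n_genes", call. = FALSE)
  }
  # constructors re-check their own invariants and name the offending key
  fitness_config(cfg$fitness$n_env_samples, cfg$fitness$env_sd,
                 cfg$fitness$eval_mode, cfg$fitness$stiffness_norm)
  do.call(anneal_config, c(cfg$anneal, list(seed = cfg$seed)))
  mutation_spec(cfg$mutation$magnitude, cfg$mutation$n_mutations,
                cfg$mutation$target, seed = cfg$seed)
  cfg
}

#' Load a run configuration
#'
#' Reads a JSON configuration file, fills in defaults for absent keys,
#' rejects unknown keys (naming the offender), and validates every section
#' through the corresponding constructor. An empty file (or `{}`) yields
#' the full default configuration. Every stochastic component of a run
#' derives its own seed from the single global `seed` via [derive_seed()]
#' with a named salt.
#'
#' @param path JSON file; may be empty.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list() else {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  cfg <- validate_config(merge_config(config_defaults(), user))
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Inverse of [load_run_config()]: `load_run_config(save_run_config(cfg))`
#' returns `cfg`.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- command-line interface ------------------------------------------------

cli_parse_flags <- function(args) {
  flags <- list()
  positional <- character()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, args[i])
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

cli_config <- function(flags) {
  cfg <- if (!is.null(flags[["config"]])) {
    load_run_config(flags[["config"]])
  } else {
    structure(validate_config(config_defaults()), class = "run_config")
  }
  if (!is.null(flags[["seed"]])) {
    cfg$seed <- as_seed_int(as.numeric(flags[["seed"]]))
    cfg <- validate_config(cfg)
  }
  cfg
}

#' Command-line entry point
#'
#' Dispatches the subcommands `evolve`, `simulate`, `theory-sweep`,
#' `experiment dual-buffering`, `experiment knockout-dim`, and
#' `fixtures make-network`. All subcommands accept `--seed <int>`,
#' `--config <file.json>` and `--out <path>`; `evolve` also accepts
#' `--net-out <file.json>` and `--ctrl-out <file.json>`, `simulate` and the
#' experiments accept `--net <file.json>` / `--ctrl <file.json>`. Invoke
#' from a shell as
#' `Rscript -e 'softmodes::softmodes_main()' evolve --seed 1 --out trace.csv`.
#'
#' @param args command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return exit status 0, invisibly.
#' @export
softmodes_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- cli_parse_flags(args)
  flags <- parsed$flags
  cmd <- paste(parsed$positional, collapse = " ")
  if (cmd == "") {
    cat("usage: evolve | simulate | theory-sweep |",
        "experiment dual-buffering | experiment knockout-dim |",
        "fixtures make-network\n")
    return(invisible(0L))
  }
  cfg <- cli_config(flags)
  out <- flags[["out"]] %||% "out.csv"
  fit_cfg <- fitness_config(cfg$fitness$n_env_samples, cfg$fitness$env_sd,
                            cfg$fitness$eval_mode, cfg$fitness$stiffness_norm)

  if (cmd == "fixtures make-network") {
    net <- random_network(cfg$n_genes, seed = derive_seed(cfg$seed, "network"))
    save_artifact(net, out)
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd == "evolve") {
    net <- if (!is.null(flags[["net"]])) load_artifact(flags[["net"]]) else {
      random_network(cfg$n_genes, seed = derive_seed(cfg$seed, "network"))
    }
    ctrl <- random_controller(cfg$n_genes, cfg$k_channels,
                              seed = derive_seed(cfg$seed, "controller"))
    ann <- do.call(anneal_config, c(cfg$anneal, list(seed = cfg$seed)))
    trace <- anneal(net, ctrl, fit_cfg, ann)
    save_artifact(trace, out)
    if (!is.null(flags[["net-out"]])) save_artifact(trace$best_network, flags[["net-out"]])
    if (!is.null(flags[["ctrl-out"]])) save_artifact(trace$best_controller, flags[["ctrl-out"]])
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd == "simulate") {
    net <- load_artifact(flags[["net"]])
    ctrl <- if (!is.null(flags[["ctrl"]])) load_artifact(flags[["ctrl"]])
    de <- withr::with_seed(
      derive_seed(cfg$seed, "simulate-env"),
      stats::rnorm(net$n_genes, sd = cfg$ensemble$env_sd)
    )
    t_end <- as.numeric(flags[["t-end"]] %||% 100)
    traj <- simulate_network(net, t_end, forcing = env_forcing(de),
                             controller = ctrl)
    export_trajectory(traj, out)
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd == "theory-sweep") {
    sweep_df <- theory_sweep(n_dims_vec = c(5, 20, 50))
    utils::write.csv(sweep_df, out, row.names = FALSE)
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd == "experiment dual-buffering") {
    fx <- evolved_fixture_pair(cfg, fit_cfg)
    res <- dual_buffering_experiment(
      fx$net_gap, fx$ctrl_gap, fx$net_nogap, fx$ctrl_nogap,
      mutation_spec(cfg$mutation$magnitude, cfg$mutation$n_mutations,
                    cfg$mutation$target, seed = derive_seed(cfg$seed, "mut")),
      env_sd = cfg$ensemble$env_sd, seed = derive_seed(cfg$seed, "dual")
    )
    utils::write.csv(as.data.frame(res), out, row.names = FALSE)
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd == "experiment knockout-dim") {
    fx <- evolved_fixture_pair(cfg, fit_cfg)
    res <- knockout_dimensionality_experiment(
      fx$net_gap, fx$ctrl_gap, env_sd = cfg$ensemble$env_sd,
      n_perturbations = cfg$ensemble$n_draws,
      seed = derive_seed(cfg$seed, "knockout-dim")
    )
    utils::write.csv(
      data.frame(
        arm = c("controlled", "knockout"),
        pc1_share = c(res$pc1_share_controlled, res$pc1_share_knockout),
        effective_rank = c(res$effective_rank_controlled,
                           res$effective_rank_knockout)
      ),
      out, row.names = FALSE
    )
    message("wrote ", out)
    return(invisible(0L))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}

#' Evolve the gap / no-gap fixture pair used by the experiments
#'
#' The gap network is obtained by co-evolving a k = 1 controller and the
#' network under selection for environmental homeostasis (the arm that
#' develops a soft mode); the no-gap network keeps its random parameters
#' fixed while only its k = 1 controller is selected for environmental
#' robustness.
#'
#' @param cfg a `run_config`.
#' @param fit_cfg a [fitness_config()] (defaults derived from `cfg`).
#' @return list with `net_gap`, `ctrl_gap`, `net_nogap`, `ctrl_nogap`, and
#'   the two [anneal()] traces `trace_gap`, `trace_nogap`.
#' @export
evolved_fixture_pair <- function(cfg, fit_cfg = NULL) {
  if (is.null(fit_cfg)) {
    fit_cfg <- fitness_config(cfg$fitness$n_env_samples, cfg$fitness$env_sd,
                              cfg$fitness$eval_mode, cfg$fitness$stiffness_norm)
  }
  net0 <- random_network(cfg$n_genes, seed = derive_seed(cfg$seed, "network"))
  ctrl0 <- random_controller(cfg$n_genes, 1L,
                             seed = derive_seed(cfg$seed, "controller"),
                             action = "aligned")
  ann_gap <- do.call(anneal_config,
                     c(cfg$anneal, list(seed = derive_seed(cfg$seed, "anneal-gap"))))
  tr_gap <- anneal(net0, ctrl0, fit_cfg, ann_gap)
  ann_ng <- do.call(anneal_config, c(
    utils::modifyList(cfg$anneal, list(mutate_network = FALSE)),
    list(seed = derive_seed(cfg$seed, "anneal-nogap"))
  ))
  tr_ng <- anneal(net0, ctrl0, fit_cfg, ann_ng)
  list(
    net_gap = tr_gap$best_network, ctrl_gap = tr_gap$best_controller,
    net_nogap = tr_ng$best_network, ctrl_nogap = tr_ng$best_controller,
    trace_gap = tr_gap, trace_nogap = tr_ng
  )
}
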