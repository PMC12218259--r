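#' Analysis configuration
#'
#' Collects every tunable of the end-to-end drivers with its default.
#' Sizes scale the expensive resampling steps; the defaults mirror the
#' full-scale analysis (10,000 circular shuffles, 500 decoder
#' iterations) and are typically reduced for quick runs.
#'
#' @param mode `"social"` or `"maze"`.
#' @param input a `ca_session` object, a path to a session directory
#'   (see [read_session()]), or `NULL` to generate a synthetic session
#'   from the generator defaults.
#' @param dynamic synthetic social session: context switch after epoch B.
#' @param remap synthetic session: redraw the social ensemble per
#'   context.
#' @param context_link synthetic session: `"independent"` or
#'   `"shared_sign"` social/context plants.
#' @param n_neurons,baseline_rate synthetic generator parameters.
#' @param n_shuffles circular shuffles per neuron.
#' @param n_iterations decoder iterations (within-scope).
#' @param n_transfer_iterations decoder iterations (transfer).
#' @param holdout held-out fraction for within-scope decoding.
#' @param max_per_class cap on frames per class per decoder iteration.
#' @param n_permutations label permutations for similarity nulls.
#' @param highly_active_threshold activity fraction above which a neuron
#'   counts as highly active (strict).
#' @param seed master seed; every stochastic step derives from it.
#' @param out_dir if non-`NULL`, the results bundle is written there.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("social", "maze"),
                            input = NULL,
                            dynamic = TRUE,
                            remap = FALSE,
                            context_link = "independent",
                            n_neurons = 80L,
                            baseline_rate = 0.02,
                            n_shuffles = 10000L,
                            n_iterations = 500L,
                            n_transfer_iterations = 200L,
                            holdout = 0.25,
                            max_per_class = 1000L,
                            n_permutations = 10000L,
                            highly_active_threshold = 0.075,
                            seed = 1L,
                            out_dir = NULL) {
  structure(list(mode = match.arg(mode), input = input, dynamic = dynamic,
                 remap = remap, context_link = context_link,
                 n_neurons = as.integer(n_neurons),
                 baseline_rate = baseline_rate,
                 n_shuffles = as.integer(n_shuffles),
                 n_iterations = as.integer(n_iterations),
                 n_transfer_iterations = as.integer(n_transfer_iterations),
                 holdout = holdout, max_per_class = max_per_class,
                 n_permutations = as.integer(n_permutations),
                 highly_active_threshold = highly_active_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

get_session <- function(config, maze = FALSE) {
  if (inherits(config$input, "ca_session")) return(config$input)
  if (!is.null(config$input)) return(read_session(config$input))
  spec <- session_spec(
    n_neurons = config$n_neurons,
    baseline_rate = config$baseline_rate,
    epoch_plan = if (maze) maze_epoch_plan()
                 else social_epoch_plan(dynamic = config$dynamic))
  truth <- truth_config(remap = config$remap,
                        context_link = config$context_link)
  if (maze) generate_maze_session(spec, truth, seed = config$seed,
                                  make_traces = FALSE)
  else generate_session(spec, truth, seed = config$seed,
                        make_traces = FALSE)
}

#' Run the social-interaction analysis end to end
#'
#' Executes the full chain on one session: activity summaries,
#' per-epoch social/nonsocial population vectors with their similarity
#' matrix and within/between-context summary, social and context
#' modulation vectors with their similarity reports and overlap table,
#' and balanced decoding with per-epoch transfer plus the
#' degree-preserving surrogate control.
#'
#' @param config an [analysis_config()] with `mode = "social"`.
#' @return list of class `results_bundle`; written to `config$out_dir`
#'   when set.
#' @export
run_social_pipeline <- function(config = analysis_config("social")) {
  stopifnot(inherits(config, "analysis_config"), config$mode == "social")
  session <- get_session(config)
  ann <- session$annotation
  raster <- session$raster
  epochs <- unique(ann$epoch_id)
  if (!all(c("A", "B", "C", "D") %in% epochs))
    stop("annotation lacks epochs: ",
         paste(setdiff(c("A", "B", "C", "D"), epochs), collapse = ", "))
  context_map <- vapply(split(ann$context_id, ann$epoch_id),
                        function(x) x[1], character(1))

  act <- activity_summary(raster,
                          list(social = social_mask(ann),
                               nonsocial = nonsocial_mask(ann)),
                          threshold = config$highly_active_threshold)

  pv <- list(); keys <- NULL
  for (ep in c("A", "B", "C", "D")) {
    for (ty in c("social", "nonsocial")) {
      m <- if (ty == "social") social_mask(ann, ep) else nonsocial_mask(ann, ep)
      key <- paste(ep, ty, sep = "_")
      pv[[key]] <- population_vector(raster, m, key)
      keys <- rbind(keys, data.frame(epoch = ep, type = ty))
    }
  }
  sim <- similarity_matrix(pv)
  wb <- within_between_summary(sim, keys, context_map)

  set.seed(config$seed + 1L)
  mod <- list(
    social_AB = behavior_modulation(raster, ann, c("A", "B"),
                                    contrast = "difference",
                                    n_shuffles = config$n_shuffles),
    social_CD = behavior_modulation(raster, ann, c("C", "D"),
                                    contrast = "difference",
                                    n_shuffles = config$n_shuffles),
    context = context_modulation(raster, ann,
                                 n_shuffles = config$n_shuffles))
  geom <- similarity_report_matrix(mod, metric = "cosine",
                                   n_permutations = config$n_permutations,
                                   seed = config$seed + 2L)
  overlap <- overlap_table(mod$social_AB, mod$context)

  task <- decode_task(social_mask(ann), nonsocial_mask(ann),
                      n_iterations = config$n_iterations,
                      holdout = config$holdout,
                      max_per_class = config$max_per_class,
                      seed = config$seed + 3L)
  dec <- train_eval(raster, task)
  sur <- surrogate_shuffle(raster, seed = config$seed + 4L)
  task_sur <- decode_task(social_mask(ann), nonsocial_mask(ann),
                          n_iterations = config$n_iterations,
                          holdout = config$holdout,
                          max_per_class = config$max_per_class,
                          seed = config$seed + 5L)
  dec_sur <- train_eval(sur, task_sur)

  ## per-epoch transfer: train on one epoch, test on the other three
  transfer <- list()
  for (ep in c("A", "B", "C", "D")) {
    others <- setdiff(c("A", "B", "C", "D"), ep)
    tm <- lapply(others, function(o)
      list(social_mask(ann, o), nonsocial_mask(ann, o)))
    names(tm) <- others
    transfer[[ep]] <- transfer_eval(
      raster, list(social_mask(ann, ep), nonsocial_mask(ann, ep)), tm,
      n_iterations = config$n_transfer_iterations,
      max_per_class = config$max_per_class,
      seed = config$seed + 6L)
  }

  bundle <- structure(list(
    mode = "social",
    activity = act,
    population_vectors = pv,
    similarity = sim,
    within_between = wb,
    modulation = mod,
    geometry = geom,
    overlap = overlap,
    decoding = dec,
    decoding_surrogate = dec_sur,
    transfer = transfer,
    truth = session$truth,
    config = config,
    provenance = provenance(config)),
    class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Run the anxiety/maze analysis end to end
#'
#' Arm-wise population vectors with their similarity matrix, maze-vs-
#' home-cage and open-arm (and T-maze arm) modulation vectors with
#' similarity reports, and the cross-maze decoder transfer grid
#' (context discrimination generalizing across mazes; open-vs-closed
#' discrimination transferring between EZM and EPM but not from context
#' training).
#'
#' @param config an [analysis_config()] with `mode = "maze"`.
#' @return list of class `results_bundle`.
#' @export
run_maze_pipeline <- function(config = analysis_config("maze")) {
  stopifnot(inherits(config, "analysis_config"), config$mode == "maze")
  session <- get_session(config, maze = TRUE)
  ann <- session$annotation
  raster <- session$raster
  mazes <- intersect(c("EZM", "EPM", "TM"), unique(ann$epoch_id))
  if (length(mazes) == 0L) stop("annotation has no maze epochs")
  hc <- grep("^HC", unique(ann$epoch_id), value = TRUE)

  pv <- list()
  for (ep in hc)
    pv[[ep]] <- population_vector(raster, epoch_mask(ann, ep), ep)
  for (m in mazes) {
    for (arm in maze_arms(m)) {
      msk <- arm_mask(ann, arm) & epoch_mask(ann, m)
      if (any(msk)) pv[[arm]] <- population_vector(raster, msk, arm)
      ## an arm never visited carries no vector (undefined), as when an
      ## animal fails to explore it
    }
  }
  sim <- similarity_matrix(pv)

  set.seed(config$seed + 1L)
  mod <- list()
  if (length(hc) >= 2L)
    mod$HC1_vs_HC2 <- region_modulation(
      raster,
      which(epoch_mask(ann, hc[1:2])),
      which(epoch_mask(ann, hc[1])),
      label = "HC1-vs-HC2", n_shuffles = config$n_shuffles)
  for (m in mazes)
    mod[[paste0(m, "_vs_HC")]] <-
      maze_modulation(raster, ann, m, n_shuffles = config$n_shuffles)
  for (m in intersect(mazes, c("EZM", "EPM"))) {
    arms <- maze_arms(m)
    mod[[paste0(m, "_open")]] <-
      arm_modulation(raster, ann, m, arms[is_open_arm(arms)],
                     n_shuffles = config$n_shuffles)
  }
  if ("TM" %in% mazes)
    mod$TM_long <- arm_modulation(raster, ann, "TM", "TM_long",
                                  n_shuffles = config$n_shuffles)
  geom <- similarity_report_matrix(mod, metric = "cosine",
                                   n_permutations = config$n_permutations,
                                   seed = config$seed + 2L)

  ## decoder transfer grid: context tasks (maze vs adjacent HC) and arm
  ## tasks (open vs closed; TM long vs short)
  grid_masks <- list()
  eps <- rle(ann$epoch_id)$values
  for (m in mazes) {
    pos <- which(eps == m)
    adj <- eps[c(pos - 1L, pos + 1L)]
    adj <- adj[!is.na(adj) & grepl("^HC", adj)]
    grid_masks[[paste0(m, "_vs_HC")]] <-
      list(epoch_mask(ann, m), epoch_mask(ann, adj))
  }
  for (m in intersect(mazes, c("EZM", "EPM"))) {
    arms <- maze_arms(m)
    grid_masks[[paste0(m, "_open_vs_closed")]] <-
      list(arm_mask(ann, arms[is_open_arm(arms)]) & epoch_mask(ann, m),
           arm_mask(ann, arms[!is_open_arm(arms)]) & epoch_mask(ann, m))
  }
  if ("TM" %in% mazes)
    grid_masks$TM_long_vs_short <-
      list(arm_mask(ann, "TM_long") & epoch_mask(ann, "TM"),
           arm_mask(ann, c("TM_short1", "TM_short2")) & epoch_mask(ann, "TM"))
  transfer <- list()
  for (tr_nm in names(grid_masks)) {
    test_nms <- setdiff(names(grid_masks), tr_nm)
    ## only test on scopes frame-disjoint from the training scope
    tr_frames <- which(grid_masks[[tr_nm]][[1]] | grid_masks[[tr_nm]][[2]])
    ok <- vapply(test_nms, function(nm) {
      te <- which(grid_masks[[nm]][[1]] | grid_masks[[nm]][[2]])
      length(intersect(tr_frames, te)) == 0L
    }, logical(1))
    if (!any(ok)) next
    transfer[[tr_nm]] <- transfer_eval(
      raster, grid_masks[[tr_nm]], grid_masks[test_nms[ok]],
      n_iterations = config$n_transfer_iterations,
      max_per_class = config$max_per_class,
      seed = config$seed + 3L)
  }

  ## arm occupancy summary (dwell fractions per maze)
  occupancy <- do.call(rbind, lapply(mazes, function(m) {
    a <- ann$arm[ann$epoch_id == m]
    tab <- table(a)
    data.frame(maze = m, arm = names(tab),
               fraction = as.numeric(tab) / length(a))
  }))

  bundle <- structure(list(
    mode = "maze",
    population_vectors = pv,
    similarity = sim,
    occupancy = occupancy,
    modulation = mod,
    geometry = geom,
    transfer = transfer,
    truth = session$truth,
    config = config,
    provenance = provenance(config)),
    class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

provenance <- function(config) {
  cfgfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfgfile)
  hash <- unname(tools::md5sum(cfgfile))
  unlink(cfgfile)
  list(config_hash = hash, seed = config$seed,
       package_version = as.character(utils::packageVersion("caensemble")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a results bundle as a directory of delimited tables
#'
#' @param bundle a `results_bundle`.
#' @param path output directory.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(path, f), sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$activity)) wt(bundle$activity$summary, "activity_summary.tsv")
  if (!is.null(bundle$similarity)) {
    m <- as.data.frame(unclass(bundle$similarity))
    m <- cbind(key = rownames(m), m)
    wt(m, "similarity_matrix.tsv")
  }
  if (!is.null(bundle$within_between)) wt(bundle$within_between, "within_between.tsv")
  if (!is.null(bundle$occupancy)) wt(bundle$occupancy, "arm_occupancy.tsv")
  if (!is.null(bundle$modulation)) {
    mv <- do.call(rbind, lapply(names(bundle$modulation), function(nm) {
      v <- bundle$modulation[[nm]]
      data.frame(vector = nm, neuron = v$neuron,
                 scope = attr(v, "scope"), contrast = attr(v, "contrast"),
                 index = v$index, excluded = v$excluded)
    }))
    wt(mv, "modulation_vectors.tsv")
  }
  if (!is.null(bundle$geometry)) {
    g <- bundle$geometry
    df <- data.frame(pair1 = rownames(g$observed)[row(g$observed)[upper.tri(g$observed)]],
                     pair2 = colnames(g$observed)[col(g$observed)[upper.tri(g$observed)]],
                     observed = g$observed[upper.tri(g$observed)],
                     null_mean = g$null_mean[upper.tri(g$null_mean)],
                     percentile = g$percentile[upper.tri(g$percentile)])
    wt(df, "geometry_similarity.tsv")
  }
  if (!is.null(bundle$overlap)) {
    ov <- as.data.frame(as.table(unclass(bundle$overlap)[1:3, 1:3]))
    names(ov) <- c("v1_category", "v2_category", "count")
    wt(ov, "overlap_table.tsv")
  }
  if (!is.null(bundle$decoding)) {
    d <- rbind(cbind(data = "real", bundle$decoding$summary),
               cbind(data = "surrogate", bundle$decoding_surrogate$summary))
    wt(d, "decoding.tsv")
  }
  if (!is.null(bundle$transfer) && length(bundle$transfer) > 0) {
    tt <- do.call(rbind, lapply(names(bundle$transfer), function(nm)
      cbind(train = nm, bundle$transfer[[nm]])))
    wt(tt, "transfer.tsv")
  }
  yaml::write_yaml(bundle$provenance, file.path(path, "manifest.yaml"))
  yaml::write_yaml(unclass(bundle$config), file.path(path, "config.yaml"))
  invisible(path)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions. Subcommands:
#' `simulate` (generate and write a synthetic session), `detect-events`
#' (traces file to raster file), `run-social`, `run-maze` (full
#' pipelines writing a results bundle), and `report` (print a bundle's
#' manifest). Options: `--config <yaml>`, `--seed <int>`, `--out <dir>`,
#' `--mode social|maze`, `--input <dir>`, `--log-level quiet|info`.
#'
#' @param argv character vector of arguments (excluding the program
#'   name).
#' @return integer exit code (0 on success).
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: caensemble <simulate|detect-events|run-social|run-maze|report>",
        "[--config FILE] [--seed N] [--out DIR] [--input DIR]",
        "[--mode social|maze] [--log-level quiet|info]\n")
    1L
  }
  if (length(argv) == 0L) return(usage())
  cmd <- argv[1]
  opts <- list(seed = 1L, out = NULL, config = NULL, input = NULL,
               mode = "social", log_level = "info")
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(argv)) {
      message("unknown or incomplete option: ", argv[i])
      return(usage())
    }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts$seed <- as.integer(opts$seed)
  info <- function(...) if (opts$log_level != "quiet") message(...)
  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) { message("error: ", conditionMessage(e)); 1L })
  }
  switch(cmd,
    simulate = run({
      if (is.null(opts$out)) stop("simulate requires --out")
      maze <- identical(opts$mode, "maze")
      cfg <- base_config_from(opts)
      s <- get_session(cfg, maze = maze)
      write_session(s, opts$out)
      info("session written to ", opts$out)
    }),
    `detect-events` = run({
      if (is.null(opts$input) || is.null(opts$out))
        stop("detect-events requires --input and --out")
      tf <- file.path(opts$input, "traces.tsv")
      if (!file.exists(tf)) stop("missing traces file: ", tf)
      traces <- as.matrix(utils::read.table(tf, sep = "\t"))
      det <- detect_events(traces)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(det$values, file.path(opts$out, "raster.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      info("raster written to ", opts$out)
    }),
    `run-social` = run({
      cfg <- base_config_from(opts, mode = "social")
      run_social_pipeline(cfg)
      info("bundle written to ", cfg$out_dir)
    }),
    `run-maze` = run({
      cfg <- base_config_from(opts, mode = "maze")
      run_maze_pipeline(cfg)
      info("bundle written to ", cfg$out_dir)
    }),
    report = run({
      if (is.null(opts$input)) stop("report requires --input")
      mf <- file.path(opts$input, "manifest.yaml")
      if (!file.exists(mf)) stop("no manifest at ", mf)
      str(yaml::read_yaml(mf))
    }),
    usage())
}

base_config_from <- function(opts, mode = opts$mode) {
  over <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  over$mode <- mode
  over$seed <- opts$seed
  if (!is.null(opts$input)) over$input <- opts$input
  if (!is.null(opts$out)) over$out_dir <- opts$out
  base <- analysis_config(mode = mode)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
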