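# End-to-end orchestration: synth -> score -> fit -> classify -> eval, driven
# by one YAML config with fixed seeds. Every stage is deterministic given the
# config, writes only under the configured output directory, and never
# mutates its inputs.

#' Default pipeline configuration
#'
#' Mirrors the method's trained operating point: rotation bank +/-20 degrees
#' step 2, K = 16, subspace axes 10..50 step 10, R = 18 (capped by the axes),
#' T = 30 boosting rounds; synthetic benchmark of 10 subjects enrolled at
#' speed 1.0, trained on probes at speed 1.3, tested at 1.6, with pixel-flip
#' noise 0.02.
#'
#' @return a named list understood by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    canvas = c(64L, 44L),
    rotation = list(theta_max = 20, fine_step = 2,
                    coarse_step = NULL, coarse_max = NULL),
    K = 16L, DG = 50L, DP = 50L,
    dg_axis = seq(10L, 50L, 10L), dp_axis = seq(10L, 50L, 10L),
    R = 18L, T = 30L,
    synth = list(n_subjects = 10L, gallery_speed = 1.0,
                 train_speed = 1.3, probe_speeds = 1.6,
                 frames_per_seq = 60L, flip_noise_p = 0.02),
    seed = 1L,
    paths = list(out_dir = "emsm_run")
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  cfg
}

validate_config <- function(cfg, command) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(cfg$canvas) == 2 && all(cfg$canvas > 0), "canvas must be two positive integers")
  chk(cfg$rotation$theta_max >= 0, "rotation theta_max must be >= 0")
  chk(is.null(cfg$K) || (cfg$K >= 1 && cfg$K <= ceiling(sqrt(sum(cfg$canvas^2)))),
      "K must lie in [1, rotated image width]")
  chk(all(cfg$dg_axis >= 1) && all(cfg$dg_axis <= cfg$DG), "dg_axis must lie in [1, DG]")
  chk(all(cfg$dp_axis >= 1) && all(cfg$dp_axis <= cfg$DP), "dp_axis must lie in [1, DP]")
  chk(cfg$R >= 1, "R must be >= 1")
  chk(cfg$T >= 1, "T must be >= 1")
  chk(cfg$synth$n_subjects >= 2, "synth n_subjects must be >= 2")
  chk(cfg$synth$flip_noise_p >= 0 && cfg$synth$flip_noise_p < 1,
      "flip_noise_p must be a probability")
  chk(cfg$synth$frames_per_seq >= 2, "frames_per_seq must be >= 2")
  if (command != "synth")
    chk(dir.exists(file.path(cfg$paths$out_dir, "data")),
        sprintf("input data directory '%s' missing (run synth first)",
                file.path(cfg$paths$out_dir, "data")))
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

control_from_config <- function(cfg) {
  suppressMessages(emsm_control(
    theta_max = cfg$rotation$theta_max, fine_step = cfg$rotation$fine_step,
    coarse_step = cfg$rotation$coarse_step,
    coarse_max = cfg$rotation$coarse_max,
    K = cfg$K, DG = cfg$DG, DP = cfg$DP, dg_axis = cfg$dg_axis,
    dp_axis = cfg$dp_axis, R = cfg$R, T = cfg$T, canvas = cfg$canvas))
}

write_benchmark <- function(bench, data_dir) {
  rows <- NULL
  for (cl in names(bench$gallery)) {
    p <- file.path("gallery", cl, "seq_01")
    save_sequence(bench$gallery[[cl]], file.path(data_dir, p))
    rows <- rbind(rows, data.frame(sequence_path = p, class_id = cl,
                                   speed = bench$gallery[[cl]]$speed,
                                   role = "gallery"))
  }
  for (pid in names(bench$probes)) {
    s <- bench$probes[[pid]]
    p <- file.path("probe", pid)
    save_sequence(s, file.path(data_dir, p))
    rows <- rbind(rows, data.frame(sequence_path = p, class_id = s$class_label,
                                   speed = s$speed, role = "probe"))
  }
  utils::write.table(rows, file.path(data_dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(rows)
}

read_benchmark <- function(data_dir) {
  lab <- utils::read.delim(file.path(data_dir, "labels.tsv"),
                           stringsAsFactors = FALSE)
  gallery <- list(); probes <- list()
  for (i in seq_len(nrow(lab))) {
    s <- load_sequence(file.path(data_dir, lab$sequence_path[i]),
                       class_label = lab$class_id[i], speed = lab$speed[i])
    if (lab$role[i] == "gallery") gallery[[lab$class_id[i]]] <- s
    else probes[[basename(lab$sequence_path[i])]] <- s
  }
  list(gallery = gallery, probes = probes, labels = lab)
}

tensor_to_long <- function(tensor, probe_id) {
  g <- attr(tensor, "grids")
  d <- expand.grid(class = g$classes, r = g$r, dG = g$dg, dP = g$dp,
                   theta = g$theta, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$similarity <- as.numeric(tensor)
  cbind(probe_id = probe_id, d)
}

long_to_tensor <- function(d) {
  classes <- sort(unique(d$class))
  rs <- sort(unique(d$r)); dgs <- sort(unique(d$dG))
  dps <- sort(unique(d$dP)); ths <- sort(unique(d$theta))
  tens <- array(NA_real_, dim = c(length(classes), length(rs), length(dgs),
                                  length(dps), length(ths)),
                dimnames = list(class = classes, r = rs, dg = dgs, dp = dps,
                                theta = ths))
  idx <- cbind(match(d$class, classes), match(d$r, rs), match(d$dG, dgs),
               match(d$dP, dps), match(d$theta, ths))
  tens[idx] <- d$similarity
  structure(tens, class = "similarity_tensor",
            probe_id = d$probe_id[1],
            grids = list(classes = classes, r = rs, dg = dgs, dp = dps,
                         theta = ths))
}

#' Run one stage of the gait-recognition pipeline
#'
#' Stages: `synth` generates the synthetic benchmark and writes frames plus
#' `labels.tsv`; `score` computes similarity tensors of every probe and
#' writes them as a long TSV; `fit` boosts the training probes (those whose
#' speed equals `synth$train_speed`) into a strong classifier JSON;
#' `classify` applies the strong classifier to the remaining probes and
#' writes predictions and per-class scores; `eval` computes CCR/EER and an
#' ROC table. All outputs land under `paths$out_dir`.
#'
#' @param config a config list or path to a YAML file; see
#'   [default_config()] for the schema and defaults.
#' @param command one of `"synth"`, `"score"`, `"fit"`, `"classify"`,
#'   `"eval"`, or `"all"`.
#' @return the stage's main artifact, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         command = c("all", "synth", "score", "fit",
                                     "classify", "eval")) {
  command <- match.arg(command)
  cfg <- read_run_config(config)
  if (command == "all") {
    for (cmd in c("synth", "score", "fit", "classify", "eval"))
      out <- run_pipeline(cfg, cmd)
    return(invisible(out))
  }
  validate_config(cfg, command)
  out_dir <- cfg$paths$out_dir
  data_dir <- file.path(out_dir, "data")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (command == "synth") {
    sy <- cfg$synth
    bench <- make_benchmark(sy$n_subjects, sy$gallery_speed,
                            probe_speeds = c(sy$train_speed, sy$probe_speeds),
                            frames_per_seq = sy$frames_per_seq,
                            seed = cfg$seed, flip_noise_p = sy$flip_noise_p,
                            canvas = cfg$canvas)
    rows <- write_benchmark(bench, data_dir)
    return(invisible(rows))
  }

  bench <- read_benchmark(data_dir)
  ctl <- control_from_config(cfg)

  if (command == "score") {
    model <- build_gallery_model(bench$gallery, ctl$grid, K = ctl$K,
                                 DG = ctl$DG)
    long <- NULL
    for (pid in names(bench$probes)) {
      tn <- similarity_tensor(probe = bench$probes[[pid]], model = model,
                              DP = ctl$DP, R = ctl$R, dg_axis = ctl$dg_axis,
                              dp_axis = ctl$dp_axis, probe_id = pid)
      long <- rbind(long, tensor_to_long(tn, pid))
    }
    path <- file.path(out_dir, "similarities.tsv")
    utils::write.table(long, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }

  sims <- utils::read.delim(file.path(out_dir, "similarities.tsv"),
                            stringsAsFactors = FALSE)
  lab <- bench$labels[bench$labels$role == "probe", ]
  lab$pid <- basename(lab$sequence_path)
  is_train <- lab$speed == cfg$synth$train_speed

  if (command == "fit") {
    train_ids <- lab$pid[is_train]
    tensors <- lapply(train_ids,
                      function(p) long_to_tensor(sims[sims$probe_id == p, ]))
    H <- fit_boost(tensors, lab$class_id[match(train_ids, lab$pid)],
                   T = cfg$T)
    path <- file.path(out_dir, "model.json")
    write_strong_classifier(H, path)
    return(invisible(path))
  }

  if (command == "classify") {
    H <- read_strong_classifier(file.path(out_dir, "model.json"))
    test_ids <- lab$pid[!is_train]
    res <- lapply(test_ids, function(p)
      suppressMessages(strong_classify(H, long_to_tensor(
        sims[sims$probe_id == p, ]))))
    scores <- do.call(rbind, lapply(res, `[[`, "scores"))
    tab <- score_table(scores, lab$class_id[match(test_ids, lab$pid)],
                       vapply(res, `[[`, character(1), "label"),
                       probe_id = test_ids)
    utils::write.table(tab, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    long <- data.frame(probe_id = rep(test_ids, each = ncol(scores)),
                       class = rep(colnames(scores), length(test_ids)),
                       score = as.numeric(t(scores)))
    utils::write.table(long, file.path(out_dir, "scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }

  # eval
  tab <- utils::read.delim(file.path(out_dir, "predictions.tsv"),
                           stringsAsFactors = FALSE)
  long <- utils::read.delim(file.path(out_dir, "scores.tsv"),
                            stringsAsFactors = FALSE)
  truth <- tab$true_class[match(long$probe_id, tab$probe_id)]
  genuine <- long$score[long$class == truth]
  impostor <- long$score[long$class != truth]
  curve <- roc_curve(genuine, impostor)
  metrics <- list(ccr = ccr(tab), eer = eer(curve), n_probes = nrow(tab))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(curve, file.path(out_dir, "roc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(metrics)
}
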