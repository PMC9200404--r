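#' Condition-averaged ERP epoch
#'
#' One participant's trial-averaged waveform for one condition: a matrix of
#' electrodes by time samples, in microvolts. Sample `i` (1-based) is at
#' `epoch_start + (i - 1) * 1000 / sampling_rate` milliseconds relative to
#' stimulus onset.
#'
#' @param participant_id Participant identifier (string).
#' @param condition Condition label (string).
#' @param data Numeric matrix `[n_electrodes x n_samples]`, microvolts, with
#'   rownames the electrode labels.
#' @param sampling_rate Sampling rate in Hz (default 128).
#' @param epoch_start Epoch start in ms relative to stimulus onset
#'   (default -200).
#' @return An object of class `erp_epoch`.
#' @export
erp_epoch <- function(participant_id, condition, data,
                      sampling_rate = 128, epoch_start = -200) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(rownames(data))) stop("epoch data must have electrode rownames")
  if (ncol(data) < 2L) stop("an epoch needs at least 2 samples")
  if (any(!is.finite(data))) stop("epoch data must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  structure(
    list(participant_id = as.character(participant_id),
         condition = as.character(condition),
         data = data,
         sampling_rate = as.numeric(sampling_rate),
         epoch_start = as.numeric(epoch_start)),
    class = "erp_epoch")
}

#' Sample times of an epoch in milliseconds
#'
#' @param erp An `erp_epoch`.
#' @return Numeric vector of length `ncol(erp$data)`.
#' @export
epoch_times <- function(erp) {
  erp$epoch_start + (seq_len(ncol(erp$data)) - 1) * 1000 / erp$sampling_rate
}

#' An SPN experiment: participants, conditions and metadata
#'
#' Bundles per-participant condition averages with the experiment metadata
#' used throughout the catalogue analyses: sample size, W-load (regularity
#' salience on a 0-1 scale), task relevance, publication status, and the
#' electrode cluster / time window used in the original analysis.
#'
#' @param id Experiment identifier, unique within a catalogue.
#' @param project Project identifier (free text).
#' @param participants Named list (by participant id); each element is a
#'   named list of `erp_epoch` objects, one per condition.
#' @param contrast Length-2 character vector `c(regular, random)` naming the
#'   designated contrast pair; the SPN difference is regular minus random.
#' @param w_load W-load in `[0, 1]`.
#' @param task_relevant 0 or 1: was regularity task relevant?
#' @param published Logical.
#' @param original_cluster Character vector of electrode labels used in the
#'   original analysis.
#' @param original_window Length-2 numeric, ms, half-open `[start, end)`.
#' @return An object of class `spn_experiment`.
#' @export
spn_experiment <- function(id, project = "", participants, contrast,
                           w_load = 0, task_relevant = 0, published = FALSE,
                           original_cluster = c("PO7", "O1", "O2", "PO8"),
                           original_window = c(300, 1000)) {
  if (length(contrast) != 2L) stop("contrast must name two conditions")
  if (length(participants) < 2L) {
    stop("experiment '", id, "': need at least 2 participants")
  }
  if (is.null(names(participants)) || anyDuplicated(names(participants))) {
    stop("participants must be a uniquely named list")
  }
  conditions <- unique(unlist(lapply(participants, names)))
  for (pid in names(participants)) {
    have <- names(participants[[pid]])
    miss <- setdiff(conditions, have)
    if (length(miss)) {
      stop("experiment '", id, "': participant '", pid,
           "' is missing condition(s): ", paste(miss, collapse = ", "))
    }
  }
  if (!all(contrast %in% conditions)) {
    stop("experiment '", id, "': contrast conditions not all present")
  }
  if (!is.numeric(w_load) || w_load < 0 || w_load > 1) {
    stop("w_load must lie in [0, 1]")
  }
  if (!task_relevant %in% c(0, 1)) stop("task_relevant must be 0 or 1")
  if (length(original_window) != 2L ||
      original_window[1L] >= original_window[2L]) {
    stop("original_window must be (start, end) with start < end")
  }
  ref <- participants[[1L]][[1L]]
  t0 <- ref$epoch_start
  t1 <- t0 + ncol(ref$data) * 1000 / ref$sampling_rate
  if (original_window[1L] < t0 || original_window[2L] > t1) {
    stop("experiment '", id, "': original_window lies outside the epoch")
  }
  structure(
    list(id = as.character(id), project = as.character(project),
         conditions = conditions,
         contrast = stats::setNames(as.character(contrast),
                                    c("regular", "random")),
         participants = participants,
         n = length(participants),
         w_load = as.numeric(w_load),
         task_relevant = as.integer(task_relevant),
         published = isTRUE(published),
         original_cluster = as.character(original_cluster),
         original_window = as.numeric(original_window)),
    class = "spn_experiment")
}

#' An SPN catalogue
#'
#' @param montage An `spn_montage` shared by all experiments.
#' @param experiments List of `spn_experiment` objects with unique ids.
#' @param provenance Free-text provenance notes.
#' @return An object of class `spn_catalogue`.
#' @export
spn_catalogue <- function(montage, experiments = list(), provenance = "") {
  validate_montage(montage)
  ids <- vapply(experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("experiment ids are not unique")
  names(experiments) <- ids
  cat <- structure(
    list(montage = montage, experiments = experiments,
         provenance = as.character(provenance)),
    class = "spn_catalogue")
  validate_catalogue(cat)
  cat
}

#' Validate a catalogue against its type invariants
#'
#' @param catalogue An `spn_catalogue`.
#' @return The catalogue, invisibly, if valid.
#' @export
validate_catalogue <- function(catalogue) {
  stopifnot(inherits(catalogue, "spn_catalogue"))
  validate_montage(catalogue$montage)
  labels <- catalogue$montage$labels
  for (exp in catalogue$experiments) {
    bad <- setdiff(exp$original_cluster, labels)
    if (length(bad)) {
      stop("experiment '", exp$id, "' references electrode(s) absent from ",
           "the montage: ", paste(bad, collapse = ", "))
    }
    for (pid in names(exp$participants)) {
      for (cond in names(exp$participants[[pid]])) {
        e <- exp$participants[[pid]][[cond]]
        if (!identical(rownames(e$data), labels)) {
          stop("experiment '", exp$id, "', participant '", pid,
               "', condition '", cond,
               "': electrode rows do not match the montage")
        }
      }
    }
  }
  invisible(catalogue)
}

#' @export
print.spn_catalogue <- function(x, ...) {
  ns <- vapply(x$experiments, function(e) e$n, numeric(1))
  cat("<spn_catalogue> ", length(x$experiments), " experiments, ",
      sum(ns), " participants, ", length(x$montage$labels),
      "-channel montage\n", sep = "")
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write a catalogue to its plain-text interchange layout
#'
#' The layout is `catalogue.json` (manifest), `montage.json`, and per
#' experiment `experiments/<id>/meta.json` plus one tab-separated file per
#' participant and condition (`time_ms` column then electrodes in montage
#' order, one row per sample). Values are written with 10 significant digits
#' so a load/save round trip is lossless at working precision.
#'
#' @param catalogue A valid `spn_catalogue`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
save_catalogue <- function(catalogue, path) {
  validate_catalogue(catalogue)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory '", path, "'")
  m <- catalogue$montage
  jsonlite::write_json(
    list(format_version = 1L,
         montage_file = "montage.json",
         experiments = as.list(names(catalogue$experiments)),
         provenance = catalogue$provenance),
    file.path(path, "catalogue.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(labels = as.list(m$labels),
         positions = lapply(seq_along(m$labels), function(i) {
           list(label = m$labels[i], x = m$positions[i, 1L],
                y = m$positions[i, 2L], z = m$positions[i, 3L])
         }),
         neighbours = apply(m$neighbours, 1L, as.list),
         adjacency_threshold = m$adjacency_threshold),
    file.path(path, "montage.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (exp in catalogue$experiments) {
    edir <- file.path(path, "experiments", exp$id)
    ref <- exp$participants[[1L]][[1L]]
    jsonlite::write_json(
      list(id = exp$id, project = exp$project, n = exp$n,
           conditions = as.list(exp$conditions),
           contrast = as.list(exp$contrast),
           participants = as.list(names(exp$participants)),
           w_load = exp$w_load, task_relevant = exp$task_relevant,
           published = exp$published,
           original_cluster = as.list(exp$original_cluster),
           original_window = exp$original_window,
           sampling_rate = ref$sampling_rate,
           epoch_start = ref$epoch_start),
      {
        dir.create(edir, recursive = TRUE, showWarnings = FALSE)
        file.path(edir, "meta.json")
      },
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (pid in names(exp$participants)) {
      pdir <- file.path(edir, "participants", pid)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (cond in names(exp$participants[[pid]])) {
        e <- exp$participants[[pid]][[cond]]
        tab <- cbind(time_ms = fmt_num(epoch_times(e)),
                     apply(t(e$data), 2L, fmt_num))
        colnames(tab) <- c("time_ms", rownames(e$data))
        utils::write.table(tab, file.path(pdir, paste0(cond, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(path)
}

read_epoch_tsv <- function(file, labels, pid, cond, sampling_rate,
                           epoch_start) {
  raw <- utils::read.delim(file, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  bad <- setdiff(setdiff(colnames(raw), "time_ms"), labels)
  if (length(bad)) {
    stop("file '", file, "': electrode label(s) absent from montage: ",
         paste(bad, collapse = ", "))
  }
  miss <- setdiff(labels, colnames(raw))
  if (length(miss)) {
    stop("file '", file, "': missing electrode column(s): ",
         paste(miss, collapse = ", "))
  }
  num <- suppressWarnings(
    vapply(raw[labels], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, labels))
  if (anyNA(num)) {
    ij <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("file '", file, "': non-numeric value at line ", ij[1L] + 1L,
         " (electrode ", labels[ij[2L]], ")")
  }
  erp_epoch(pid, cond, t(num), sampling_rate = sampling_rate,
            epoch_start = epoch_start)
}

#' Load a catalogue from its interchange layout
#'
#' Electrode columns are normalized to montage order; participants and
#' experiments keep the order of the manifest files.
#'
#' @param path Directory containing `catalogue.json`.
#' @return A validated `spn_catalogue`.
#' @export
load_catalogue <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "catalogue.json"),
                                  simplifyVector = TRUE)
  mj <- jsonlite::read_json(file.path(path, manifest$montage_file),
                            simplifyVector = TRUE)
  montage <- build_montage(
    positions = data.frame(label = mj$positions$label, x = mj$positions$x,
                           y = mj$positions$y, z = mj$positions$z,
                           stringsAsFactors = FALSE),
    adjacency_threshold = mj$adjacency_threshold)
  labels <- montage$labels
  experiments <- lapply(manifest$experiments, function(id) {
    edir <- file.path(path, "experiments", id)
    meta <- jsonlite::read_json(file.path(edir, "meta.json"),
                                simplifyVector = TRUE)
    participants <- stats::setNames(lapply(meta$participants, function(pid) {
      eps <- stats::setNames(lapply(meta$conditions, function(cond) {
        f <- file.path(edir, "participants", pid, paste0(cond, ".tsv"))
        if (!file.exists(f)) {
          stop("experiment '", id, "': participant '", pid,
               "' is missing condition '", cond, "' (expected file ", f, ")")
        }
        read_epoch_tsv(f, labels, pid, cond, meta$sampling_rate,
                       meta$epoch_start)
      }), meta$conditions)
      eps
    }), meta$participants)
    spn_experiment(id = meta$id, project = meta$project,
                   participants = participants,
                   contrast = unlist(meta$contrast)[c("regular", "random")],
                   w_load = meta$w_load, task_relevant = meta$task_relevant,
                   published = meta$published,
                   original_cluster = meta$original_cluster,
                   original_window = meta$original_window)
  })
  spn_catalogue(montage, experiments, provenance = manifest$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
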