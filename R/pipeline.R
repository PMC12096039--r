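# Orchestration, formats, reproducibility -----------------------------------

num_fmt <- function(x) formatC(x, format = "g", digits = 17)

write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a dyad session to a directory container
#'
#' Plain-text container: `session.json` holds config, seed, conditions and
#' ground-truth kernel metadata; per participant and trial, one TSV of EEG
#' (channels in columns) and one TSV of regressors, written at full double
#' precision so a read round-trip is bit-identical.
#'
#' @param session a `dyad_session`.
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    seed = session$seed,
    config = unclass(session$config),
    conditions = session$conditions,
    kernels = lapply(session$kernels, function(k)
      list(name = k$name, peaks = k$peaks, topography = k$topography)),
    layout = session$layout)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  for (p in seq_along(session$participants)) {
    for (ti in seq_along(session$participants[[p]])) {
      tr <- session$participants[[p]][[ti]]
      eeg <- as.data.frame(apply(tr$eeg, 2, num_fmt))
      names(eeg) <- session$layout$label
      write_table(eeg, file.path(dir, sprintf("p%d_t%02d_eeg.tsv", p, ti)))
      regs <- as.data.frame(lapply(tr$regressors, num_fmt))
      write_table(regs, file.path(dir, sprintf("p%d_t%02d_regressors.tsv",
                                               p, ti)))
    }
  }
  invisible(dir)
}

#' Read a dyad session from a directory container
#' @param dir container directory written by [write_session()].
#' @return a `dyad_session` (ground-truth kernels restored).
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) stop("not a session container: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  config <- do.call(session_config, meta$config)
  conditions <- as.data.frame(meta$conditions)
  layout <- as.data.frame(meta$layout)
  kernels <- lapply(meta$kernels, function(k)
    kernel_spec(k$name, as.data.frame(k$peaks), unlist(k$topography)))
  n_trials <- nrow(conditions)
  participants <- lapply(1:2, function(p) lapply(seq_len(n_trials), function(ti) {
    eeg <- as.matrix(utils::read.delim(
      file.path(dir, sprintf("p%d_t%02d_eeg.tsv", p, ti)),
      check.names = FALSE, colClasses = "numeric"))
    dimnames(eeg) <- list(NULL, layout$label)
    regs <- utils::read.delim(
      file.path(dir, sprintf("p%d_t%02d_regressors.tsv", p, ti)),
      check.names = FALSE, colClasses = "numeric")
    structure(list(eeg = eeg, regressors = as.list(regs),
                   condition = condition_label(conditions$vision[ti],
                                               conditions$music[ti]),
                   fs = config$fs, gains = NULL),
              class = "trial_record")
  }))
  structure(list(participants = participants, conditions = conditions,
                 kernels = kernels, config = config, seed = meta$seed,
                 layout = layout),
            class = "dyad_session")
}

# Minimal EDF (16-bit) I/O ---------------------------------------------------

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1, width)  # EDF fields are fixed width
}

# numeric to at most 8 ASCII characters (EDF physical min/max fields)
edf_num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    substr(formatC(v, format = "e", digits = 0), 1, 8)
  }, character(1))
}

#' Write a multichannel recording as a minimal EDF file
#'
#' Plain EDF, 16-bit samples, one data record per second; physical scaling
#' per channel from the data range. Intended for interoperability tests and
#' small exports, not for annotations (EDF+) or long recordings.
#'
#' @param eeg time x channel matrix.
#' @param fs sampling rate, Hz (integer).
#' @param labels channel labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, fs, labels, path) {
  stopifnot(ncol(eeg) == length(labels), fs == round(fs))
  ns <- ncol(eeg)
  n_rec <- floor(nrow(eeg) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  eeg <- eeg[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(eeg, 2, min); pmax_ <- apply(eeg, 2, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  # round the physical range to its 8-character header representation so
  # writer and reader use the same scaling
  pmin_ <- as.numeric(edf_num8(pmin_ - abs(pmin_) * 1e-6))
  pmax_ <- as.numeric(edf_num8(pmax_ + abs(pmax_) * 1e-6))
  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(x, w) writeChar(paste0(edf_pad(x, w), collapse = ""), con,
                                 eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  wr(substr(labels, 1, 16), 16)
  wr(rep("", ns), 80); wr(rep("uV", ns), 8)
  wr(edf_num8(pmin_), 8)
  wr(edf_num8(pmax_), 8)
  wr(rep("-32768", ns), 8); wr(rep("32767", ns), 8)
  wr(rep("", ns), 80); wr(rep(fs, ns), 8); wr(rep("", ns), 32)
  scale_ <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((eeg[rows, ch] - pmin_[ch]) / scale_[ch]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a minimal EDF file
#' @param path EDF path.
#' @return list with `eeg` (time x channel, physical units), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  ver <- rd(8)
  if (ver != "0") stop("not an EDF file (version field '", ver, "')")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  stopifnot(header_bytes == 256 + ns * 256)
  eeg <- matrix(NA_real_, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[ch])
        stop("truncated EDF: record ", r, ", channel ", ch)
      phys <- pmin_[ch] + (dig - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      eeg[((r - 1) * spr[ch] + 1):(r * spr[ch]), ch] <- phys
    }
  }
  list(eeg = eeg, fs = spr[1] / rec_dur, labels = labels)
}

#' Read EEG from any supported source
#'
#' @param path file (EDF/delimited) or directory (session container).
#' @param format "edf", "delimited" (TSV, channels in columns, labelled
#'   header) or "container".
#' @param fs sampling rate for delimited sources, Hz.
#' @return list with `eeg`, `fs`, `labels` (container: the full session).
#' @export
read_eeg <- function(path, format = c("edf", "delimited", "container"),
                     fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
    edf = read_edf(path),
    delimited = {
      if (is.null(fs)) stop("fs is required for delimited EEG")
      df <- utils::read.delim(path, check.names = FALSE)
      list(eeg = unname(as.matrix(df)), fs = fs, labels = names(df))
    },
    container = read_session(path))
}

# Pipeline -------------------------------------------------------------------

pipeline_stages <- c("simulate", "features", "fit", "erp", "stats")

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages on a synthetic cohort and writes versioned
#' plain-text outputs plus a manifest (resolved config, seed, config hash,
#' file list) into a new run directory. Stage dependencies are enforced:
#' `features` needs `simulate`, `fit` needs `features`, `erp` and `stats`
#' need `fit`. Reruns with the same config and seed reproduce the outputs.
#'
#' @param config a [session_config()].
#' @param seed run seed.
#' @param out_dir run directory (created; must not exist).
#' @param stages subset of `c("simulate","features","fit","erp","stats")`.
#' @param n_dyads number of dyads to simulate.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = session_config(), seed = 1,
                         out_dir = tempfile("run"),
                         stages = pipeline_stages, n_dyads = 2) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  deps <- list(features = "simulate", fit = "features",
               erp = "simulate", stats = "fit")
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]], stages)
    if (length(missing_dep))
      stop("stage '", s, "' requires stage '", missing_dep[1], "'")
  }
  dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(config = unclass(config), seed = seed,
                            n_dyads = n_dyads, stages = stages),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  outputs <- character()
  emit <- function(df, name) {
    df$config_hash <- cfg_hash; df$seed <- seed
    outputs <<- c(outputs, write_table(df, file.path(out_dir, name)))
  }

  sessions <- NULL
  if ("simulate" %in% stages) {
    seeds <- derive_seeds(seed, n_dyads)
    sessions <- lapply(seeds, function(s) make_session(config, s))
    cond <- sessions[[1]]$conditions
    emit(cond, "conditions.tsv")
  }
  if ("features" %in% stages) {
    sessions <- lapply(sessions, standardize_session)
    sc <- do.call(rbind, lapply(seq_along(sessions), function(i)
      data.frame(dyad = i, participant = rep(1:2, each = ncol(sessions[[i]]$scales)),
                 series = rep(colnames(sessions[[i]]$scales), 2),
                 sd = as.vector(t(sessions[[i]]$scales)))))
    emit(sc, "regressor_scales.tsv")
  }
  partition <- NULL
  if ("fit" %in% stages) {
    participants <- unlist(lapply(sessions, `[[`, "participants"),
                           recursive = FALSE)
    partition <- trf_partition(
      participants, sessions[[1]]$conditions,
      reduced_sets = list(music = "music", self = "self", other = "other",
                          coordination = "coordination"),
      window = lag_window(fs = config$fs))
    dn <- dimnames(partition$delta_r)
    long <- expand.grid(channel = sessions[[1]]$layout$label,
                        participant = seq_len(dim(partition$delta_r)[2]),
                        condition = dn[[3]], regressor = dn[[4]],
                        KEEP.OUT.ATTRS = FALSE)
    long$delta_r <- as.vector(partition$delta_r)
    emit(long, "delta_r.tsv")
  }
  if ("erp" %in% stages) {
    win <- lag_window(fs = config$fs)
    rows <- list()
    for (si in seq_along(sessions)) for (p in 1:2) {
      trs <- sessions[[si]]$participants[[p]]
      eps <- lapply(trs, function(tr) {
        on <- detect_onsets(tr$regressors$music, config$fs, salience_sd = 3)
        ep <- epoch_eeg(tr$eeg, on$sample, win, "prestim")
        if (length(ep$kept)) apply(ep$epochs, c(2, 3), mean) else NULL
      })
      eps <- eps[!vapply(eps, is.null, logical(1))]
      m <- Reduce(`+`, eps) / length(eps)
      fz <- match("Fz", sessions[[si]]$layout$label)
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = si, participant = p, lag_ms = win$lag_ms, erp_fz = m[, fz])
    }
    emit(do.call(rbind, rows), "music_erp_fz.tsv")
  }
  if ("stats" %in% stages) {
    an <- partition_anovas(partition)
    tab <- do.call(rbind, lapply(names(an), function(rg)
      cbind(regressor = rg, an[[rg]]$anova$effects)))
    emit(tab, "anova.tsv")
  }
  manifest <- list(config_hash = cfg_hash, seed = seed, stages = stages,
                   outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
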