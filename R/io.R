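# Channel column -> FCS parameter short name ($PnN)
.fcs_channel_map <- c(
  cer_h = "BV421-H", cer_a = "BV421-A", cer_w = "BV421-W",
  fl_h = "FITC-H", fl_a = "FITC-A", fl_w = "FITC-W",
  mk_h = "PE-TxRed-H", mk_a = "PE-TxRed-A", mk_w = "PE-TxRed-W",
  sytox_h = "APC-H", sytox_a = "APC-A", sytox_w = "APC-W",
  ssc_h = "SSC-H", ssc_a = "SSC-A", ssc_w = "SSC-W"
)

#' Write events to an FCS 3.1 file
#'
#' Writes the pulse height/area/width channels as a list-mode FCS 3.1 file
#' (little-endian float32, no spillover). Truth labels are never written to
#' the FCS file; use [write_events_csv()] for a sidecar keyed by event
#' index.
#'
#' @param events `aggflux_events` table (truth columns ignored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  cols <- intersect(names(.fcs_channel_map), names(events))
  if (!length(cols)) stop("no channel columns found")
  mat <- as.matrix(events[, cols, drop = FALSE])
  storage.mode(mat) <- "double"
  n_par <- length(cols); n_tot <- nrow(mat)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_along(cols)) {
    kw[sprintf("$P%dN", i)] <- .fcs_channel_map[[cols[i]]]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(max(2^18, 2^ceiling(log2(
      max(mat[, i], 1) + 1))), scientific = FALSE)
  }
  delim <- "/"
  render_text <- function(kw) {
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }
  # fix offsets with zero-padded placeholders of stable width
  pad <- function(x) formatC(x, width = 10, flag = "0", format = "d")
  kw["$BEGINDATA"] <- pad(0); kw["$ENDDATA"] <- pad(0)
  text_start <- 58L
  text_len <- nchar(render_text(kw), type = "bytes")
  data_start <- text_start + text_len
  data_end <- data_start + 4L * n_par * n_tot - 1L
  if (n_tot == 0) data_end <- 0L
  kw["$BEGINDATA"] <- pad(if (n_tot) data_start else 0)
  kw["$ENDDATA"] <- pad(data_end)
  text <- render_text(kw)

  hdr_off <- function(x) formatC(x, width = 8, format = "d")
  header <- paste0("FCS3.1    ",
                   hdr_off(text_start), hdr_off(text_start + text_len - 1L),
                   hdr_off(if (n_tot) data_start else 0),
                   hdr_off(data_end),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n_tot > 0)
    writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the TEXT segment, validates the event count against `$TOT`, and
#' reads list-mode data in the float (`$DATATYPE F`) or unsigned integer
#' (`$DATATYPE I`, 16/32 bit) dialect with either byte order.
#'
#' @param path FCS file path.
#' @return List with `data` (data frame, columns named by `$PnN`) and
#'   `keywords` (named character vector).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!grepl("^FCS3\\.[01]", header))
    stop("not an FCS 3.0/3.1 file")
  off <- function(i) {
    s <- substr(header, 10 + (i - 1) * 8 + 1, 10 + i * 8)
    as.integer(trimws(s))
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  if (data_start == 0) data_start <- as.integer(kw[["$BEGINDATA"]])
  if (data_end == 0) data_end <- as.integer(kw[["$ENDDATA"]])
  dtype <- kw[["$DATATYPE"]]
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  pnn <- vapply(seq_len(n_par), function(i) kw[[sprintf("$P%dN", i)]], "")
  widths <- vapply(seq_len(n_par),
                   function(i) as.integer(kw[[sprintf("$P%dB", i)]]), 1L)
  if (n_tot > 0) {
    expected <- if (dtype == "F") 4L * n_par * n_tot
                else sum(widths / 8L) * n_tot
    actual <- min(data_end, file.size(path)) - data_start + 1L
    if (actual != expected)
      stop("$TOT mismatch: data segment holds ", actual,
           " bytes but $TOT implies ", expected)
    seek(con, data_start)
    if (dtype == "F") {
      vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4,
                      endian = endian)
      mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
    } else if (dtype == "I") {
      if (length(unique(widths)) != 1)
        stop("mixed-width integer parameters are not supported")
      sz <- widths[1] / 8L
      vals <- readBin(con, "integer", n = n_par * n_tot, size = sz,
                      endian = endian, signed = sz > 2)
      mat <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par,
                    byrow = TRUE)
    } else stop("unsupported $DATATYPE ", dtype)
  } else {
    mat <- matrix(numeric(0), 0, n_par)
  }
  colnames(mat) <- pnn
  miss_w <- pnn[grepl("-H$", pnn) &
                  !sub("-H$", "-W", pnn) %in% pnn]
  if (length(miss_w))
    stop("missing width parameter for channel(s): ",
         paste(sub("-H$", "", miss_w), collapse = ", "))
  list(data = as.data.frame(mat), keywords = kw)
}

#' Write events (with truth labels) as CSV
#'
#' @param events Event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read / write radial scans as CSV
#'
#' Long CSV with columns `radius_cm`, `signal`, `time_s` and header metadata
#' rows (`# key,value`) for `rotor_rpm`, `meniscus_cm`, `base_cm`, `temp_C`.
#'
#' @param scans `aggflux_scans`.
#' @param path File path.
#' @return `read_scans_csv` returns an `aggflux_scans` list.
#' @export
write_scans_csv <- function(scans, path) {
  sc1 <- scans[[1]]
  meta <- sprintf("# %s,%s", c("rotor_rpm", "meniscus_cm", "base_cm", "temp_C"),
                  c(sc1$rotor_rpm, sc1$meniscus_cm, sc1$base_cm, sc1$temp_C))
  df <- do.call(rbind, lapply(scans, function(s)
    data.frame(radius_cm = s$radius_cm, signal = s$signal,
               time_s = s$time_s)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scans_csv
#' @export
read_scans_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^# *", "", ml), ",")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  scans <- lapply(split(df, df$time_s), function(d)
    list(radius_cm = d$radius_cm, signal = d$signal, time_s = d$time_s[1],
         rotor_rpm = meta$rotor_rpm, meniscus_cm = meta$meniscus_cm,
         base_cm = meta$base_cm, temp_C = meta$temp_C))
  scans <- scans[order(vapply(scans, `[[`, numeric(1), "time_s"))]
  names(scans) <- NULL
  structure(scans, class = "aggflux_scans")
}

#' Read / write a chromatogram as CSV
#'
#' @param chrom `aggflux_chrom` data frame.
#' @param path File path.
#' @return `read_chromatogram_csv` returns an `aggflux_chrom` data frame.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("aggflux_chrom", class(out))
  out
}

# stable polynomial hash of a config, for the run manifest
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate -> instruments -> gate -> metrics -> sedimentation /
#' gel filtration -> partition for each treatment arm, writing tidy CSV
#' outputs and a JSON run manifest (config hash, seed, stage outputs) so a
#' rerun with the same configuration reproduces every CSV byte-for-byte.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `seed`, `polyQ_length`, `arms`, `n_cells`, `time_points`,
#'   `analysis_time`, `out_dir` and optional overrides `n_untransfected`,
#'   `n_particles`, `noise_sd` (chromatogram/scan noise).
#' @return The manifest, invisibly; outputs are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(arms = c("alone", "hsp40", "hsp70", "hsp40+hsp70"),
                   polyQ_length = 46, n_cells = 4000,
                   time_points = c(18, 25, 30, 46), analysis_time = 46,
                   n_untransfected = 500, n_particles = 200,
                   noise_sd = 0.02, seed = 1, out_dir = "aggflux_out")
  miss <- setdiff(names(config), names(defaults))
  if (length(miss)) stop("unknown config entries: ", paste(miss, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!all(cfg$arms %in% names(default_arm_modifiers())))
    stop("unknown arm name(s): ",
         paste(setdiff(cfg$arms, names(default_arm_modifiers())), collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    message("[aggflux] wrote ", p)
  }

  set.seed(cfg$seed)
  panel <- panel_config()
  message("[aggflux] stage: controls")
  ctl_cells <- simulate_population(sim_config(
    polyQ_length = 25, n_cells = 3000, time_points = cfg$analysis_time))
  ctl_events <- cells_to_events(ctl_cells, panel)
  untr <- cells_to_events(ctl_cells[0, ], panel, n_untransfected = 2000)
  unst <- cells_to_events(ctl_cells[0, ], panel, n_untransfected = 2000,
                          stain_sytox = FALSE)

  metrics_rows <- NULL
  partition_rows <- NULL
  for (arm in cfg$arms) {
    message("[aggflux] stage: simulate+gate arm ", arm)
    cells <- simulate_population(sim_config(
      polyQ_length = cfg$polyQ_length, n_cells = cfg$n_cells,
      time_points = cfg$time_points, arm = arm))
    snap <- cells[cells$time == cfg$analysis_time, , drop = FALSE]
    events <- cells_to_events(snap, panel,
                              n_untransfected = cfg$n_untransfected,
                              n_particles = cfg$n_particles)
    gs <- derive_gateset(events, untr, unst, ctl_events)
    labels <- apply_gates(events, gs)
    emit(cbind(event = seq_len(nrow(labels)), labels),
         sprintf("labels_%s.csv", gsub("[^a-z0-9]+", "_", arm)))

    dr <- vapply(c("all", "i", "ni"),
                 function(s) death_rate(labels, s)$rate, numeric(1))
    ifrac <- mean(labels$pulsa %in% "i" & !is.na(labels$pulsa)) /
      max(mean(!is.na(labels$pulsa)), 1e-12)
    pn <- pfr_ni_fraction(labels)
    metrics_rows <- rbind(metrics_rows, data.frame(
      arm = arm, polyQ = cfg$polyQ_length, time = cfg$analysis_time,
      death_rate_all = dr[["all"]], death_rate_i = dr[["i"]],
      death_rate_ni = dr[["ni"]], i_fraction = ifrac,
      pfr_ni_fraction = pn$fraction,
      n_transfected = sum(labels$transfected)))

    message("[aggflux] stage: biochemistry arm ", arm)
    lys <- pool_lysate(snap)
    chrom <- simulate_chromatogram(lys, noise_sd = cfg$noise_sd)
    scans <- simulate_radial_scans(
      data.frame(s = c(0, 3000),
                 signal = c((1 - lys$p_inc), lys$p_inc) * lys$total_signal),
      rotor_rpm = 3000, scan_times = seq(200, 6000, length.out = 8),
      noise_sd = cfg$noise_sd * lys$total_signal)
    pools <- decompose_pools(chrom)
    incl <- inclusion_fraction(scans)
    part <- combine_partition(pools, incl$p_inc, total = incl$total)
    partition_rows <- rbind(partition_rows, data.frame(
      arm = arm, p_mono = part$p_mono, p_olig = part$p_olig,
      p_inc = part$p_inc, total = part$total,
      true_p_mono = lys$p_mono, true_p_olig = lys$p_olig,
      true_p_inc = lys$p_inc))
  }
  emit(metrics_rows, "metrics.csv")
  emit(partition_rows, "partition.csv")

  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("aggflux")),
                   outputs = outputs,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
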