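# Multichannel record container: uniformly sampled ECG + IMU channels with
# site/lead metadata, plus provenance (seed, generator) when synthetic.

CHANNEL_KINDS <- c("ecg", "imu_x", "imu_y", "imu_z")
CHANNEL_SITES <- c("chest", "back", "none")

#' Construct a multichannel physiological record
#'
#' @param fs sampling rate, Hz.
#' @param info data frame with one row per channel and columns `label`
#'   (unique), `site` (chest/back/none), `kind` (ecg/imu_x/imu_y/imu_z) and
#'   `units` (e.g. mV, m/s2).
#' @param data numeric matrix, one column per channel (same order as `info`).
#' @param meta named list of provenance values (e.g. seed, generator).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(fs, info, data, meta = list()) {
  assert_scalar_num(fs, "fs", lower = 1e-9)
  stopifnot(is.data.frame(info), is.matrix(data))
  if (nrow(info) != ncol(data))
    stopf("channel descriptor count (%d) != data column count (%d)",
          nrow(info), ncol(data))
  if (anyDuplicated(info$label)) stopf("channel labels must be unique")
  bad <- setdiff(info$kind, CHANNEL_KINDS)
  if (length(bad)) stopf("unknown channel kind: %s", paste(bad, collapse = ", "))
  bad <- setdiff(info$site, CHANNEL_SITES)
  if (length(bad)) stopf("unknown channel site: %s", paste(bad, collapse = ", "))
  colnames(data) <- info$label
  structure(list(fs = fs, info = info, data = data, meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("Multichannel record: %d channels x %d samples at %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  print(x$info, row.names = FALSE)
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, labels = x$info$label, max_s = 10, ...) {
  n <- min(nrow(x$data), round(max_s * x$fs))
  tt <- (seq_len(n) - 1) / x$fs
  old <- graphics::par(mfrow = c(length(labels), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (lb in labels)
    graphics::plot(tt, x$data[seq_len(n), lb], type = "l", xlab = "s",
                   ylab = lb, ...)
  invisible(x)
}

# channel lookup used by the denoisers; errors name the missing site/lead
record_channel <- function(record, label) {
  if (!label %in% record$info$label)
    stopf("record lacks channel '%s'", label)
  record$data[, label]
}

find_ecg_channel <- function(record, lead, site) {
  ok <- record$info$kind == "ecg" & record$info$site == site &
    (record$info$label == paste0(site, "_", lead) |
       endsWith(record$info$label, lead))
  if (!any(ok)) stopf("record lacks required ECG channel %s/%s", site, lead)
  record$info$label[which(ok)[1]]
}

find_imu_channels <- function(record) {
  want <- c("imu_x", "imu_y", "imu_z")
  lab <- vapply(want, function(k) {
    ok <- record$info$kind == k
    if (!any(ok)) NA_character_ else record$info$label[which(ok)[1]]
  }, character(1))
  if (anyNA(lab))
    stopf("record lacks required IMU channel(s): %s",
          paste(want[is.na(lab)], collapse = ", "))
  lab
}

#' Write / read a multichannel record
#'
#' The canonical CSV dialect is plain text: a `# fs=<Hz>` header line, optional
#' `# <key>=<value>` provenance lines, one `# channel=label,site,kind,units`
#' descriptor line per channel, then comma-separated sample rows (one value per
#' channel). A minimal WFDB (format 16) writer/reader is provided for
#' interoperability: ECG signals are named `<lead>_<site>` and IMU signals
#' `imu_<axis>` in the `.hea` header, samples are stored as int16 with a
#' per-channel gain.
#'
#' @param record an [ecg_record()].
#' @param path output path (`.csv`, or the `.hea` path / record base for WFDB).
#' @param format `"csv"` or `"wfdb"`.
#' @return `read_record` returns an `ecg_record`; `write_record` returns
#'   `path` invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  if (format == "csv") write_record_csv(record, path) else write_record_wfdb(record, path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", record$fs), con)
  for (k in names(record$meta))
    writeLines(sprintf("# %s=%s", k, format(record$meta[[k]])), con)
  for (i in seq_len(nrow(record$info)))
    writeLines(sprintf("# channel=%s,%s,%s,%s", record$info$label[i],
                       record$info$site[i], record$info$kind[i],
                       record$info$units[i]), con)
  utils::write.table(format(record$data, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  head_lines <- sub("^#\\s*", "", lines[hdr])
  fs <- NULL; meta <- list(); chans <- list()
  for (h in head_lines) {
    kv <- regmatches(h, regexec("^([^=]+)=(.*)$", h))[[1]]
    if (length(kv) != 3) next
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (key == "fs") fs <- as.numeric(val)
    else if (key == "channel") {
      parts <- trimws(strsplit(val, ",")[[1]])
      if (length(parts) != 4) stopf("malformed channel descriptor: %s", val)
      chans[[length(chans) + 1L]] <- parts
    } else meta[[key]] <- val
  }
  if (is.null(fs) || !is.finite(fs)) stopf("CSV record header lacks '# fs=<Hz>'")
  if (!length(chans)) stopf("CSV record header lacks channel descriptors")
  info <- do.call(rbind.data.frame, chans)
  names(info) <- c("label", "site", "kind", "units")
  data_lines <- which(!hdr & nzchar(trimws(lines)))
  vals <- strsplit(lines[data_lines], ",", fixed = TRUE)
  nf <- lengths(vals)
  if (any(nf != nrow(info)))
    stopf("row at line %d has %d values, expected %d",
          data_lines[which(nf != nrow(info))[1]],
          nf[which(nf != nrow(info))[1]], nrow(info))
  data <- matrix(as.numeric(unlist(vals)), ncol = nrow(info), byrow = TRUE)
  if (anyNA(data)) stopf("non-numeric sample value in record CSV")
  ecg_record(fs, info, data, meta)
}

# --- minimal WFDB format-16 support ---------------------------------------

wfdb_paths <- function(path) {
  base <- sub("\\.hea$", "", path)
  list(base = basename(base), hea = paste0(base, ".hea"),
       dat = paste0(base, ".dat"))
}

wfdb_signal_name <- function(info_row) {
  if (info_row$kind == "ecg") {
    lead <- sub(paste0("^", info_row$site, "_"), "", info_row$label)
    paste0(lead, "_", info_row$site)
  } else info_row$kind
}

write_record_wfdb <- function(record, path) {
  p <- wfdb_paths(path)
  nsig <- ncol(record$data); nsamp <- nrow(record$data)
  gain <- apply(record$data, 2, function(x) {
    m <- max(abs(x)); if (m == 0) 200 else 30000 / m
  })
  dig <- round(sweep(record$data, 2, gain, `*`))
  dig[dig > 32767] <- 32767; dig[dig < -32768] <- -32768
  hdr <- sprintf("%s %d %.10g %d", p$base, nsig, record$fs, nsamp)
  sig <- vapply(seq_len(nsig), function(i) {
    sprintf("%s 16 %.10g(0)/%s 16 0 %d 0 0 %s",
            paste0(p$base, ".dat"), gain[i], record$info$units[i],
            as.integer(dig[1, i]), wfdb_signal_name(record$info[i, ]))
  }, character(1))
  writeLines(c(hdr, sig), p$hea)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
}

read_record_wfdb <- function(path) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea)) stopf("no such WFDB header: %s", p$hea)
  lines <- readLines(p$hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  info <- list(); gain <- numeric(nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gspec <- f[3]
    gm <- regmatches(gspec, regexec("^([-0-9.eE+]+)(\\(([-0-9.]+)\\))?(/(.*))?$", gspec))[[1]]
    gain[i] <- as.numeric(gm[2])
    units <- if (nzchar(gm[6])) gm[6] else "mV"
    name <- f[length(f)]
    if (startsWith(name, "imu_")) {
      info[[i]] <- data.frame(label = name, site = "none", kind = name,
                              units = units)
    } else {
      parts <- strsplit(name, "_", fixed = TRUE)[[1]]
      lead <- paste(parts[-length(parts)], collapse = "_")
      site <- parts[length(parts)]
      info[[i]] <- data.frame(label = paste0(site, "_", lead), site = site,
                              kind = "ecg", units = units)
    }
  }
  info <- do.call(rbind, info)
  con <- file(p$dat, "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = nsig * nsamp, size = 2, endian = "little",
                 signed = TRUE)
  data <- matrix(raw, ncol = nsig, byrow = TRUE)
  data <- sweep(data, 2, gain, `/`)
  ecg_record(fs, info, data)
}
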