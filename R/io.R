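# Plain-text dataset interchange: per-subject TSV matrices plus a CSV
# manifest. (No EDF/NPZ dependency exists in this stack; the archive
# route keeps everything greppable and portable.)

#' Write a dataset of recordings to a directory
#'
#' One gzip-free TSV per subject (rows = channels, columns = samples)
#' plus `manifest.csv` with subject_id, label, domain_id, file,
#' sampling_rate and channel names.
#'
#' @param recordings list of [eeg_recording()] objects.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(r) {
    fn <- paste0(r$subject_id, ".tsv")
    utils::write.table(r$data, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    data.frame(subject_id = r$subject_id, label = r$label,
               domain_id = r$domain_id, file = fn,
               sampling_rate = r$sampling_rate,
               channels = paste(r$channel_names, collapse = ";"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return list of [eeg_recording()] objects.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    dat <- as.matrix(utils::read.table(file.path(dir, m$file), sep = "\t"))
    dimnames(dat) <- NULL
    eeg_recording(dat, m$sampling_rate,
                  channel_names = strsplit(m$channels, ";")[[1]],
                  subject_id = m$subject_id, label = as.integer(m$label),
                  domain_id = m$domain_id)
  })
}

#' Write a lead field to plain-text files
#'
#' `leadfield.tsv` (dense gain matrix) and `roi_map.csv`
#' (source_index, roi_index, roi_name).
#'
#' @param lead_field a [make_lead_field()] result.
#' @param dir output directory.
#' @export
write_lead_field <- function(lead_field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(lead_field$K, file.path(dir, "leadfield.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.csv(
    data.frame(source_index = seq_along(lead_field$roi_of_source),
               roi_index = lead_field$roi_of_source,
               roi_name = lead_field$roi_names[lead_field$roi_of_source]),
    file.path(dir, "roi_map.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Read a lead field written by [write_lead_field()]
#'
#' @param dir directory with `leadfield.tsv` and `roi_map.csv`.
#' @return a `lead_field` list.
#' @export
read_lead_field <- function(dir) {
  K <- as.matrix(utils::read.table(file.path(dir, "leadfield.tsv"),
                                   sep = "\t"))
  dimnames(K) <- NULL
  map <- utils::read.csv(file.path(dir, "roi_map.csv"))
  roi_names <- tapply(map$roi_name, map$roi_index, `[`, 1)
  structure(list(K = K, roi_of_source = as.integer(map$roi_index),
                 roi_names = as.character(roi_names)),
            class = "lead_field")
}

#' Write model samples (features + graphs) to a directory
#'
#' Per epoch: a features CSV (`X`) and an adjacency TSV (`A_hat`), plus
#' `samples.csv` manifest.
#'
#' @param samples list from [epochs_to_samples()].
#' @param dir output directory.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    xf <- sprintf("%s_ep%03d_X.csv", s$subject_id, s$epoch_index)
    af <- sprintf("%s_ep%03d_A.tsv", s$subject_id, s$epoch_index)
    utils::write.csv(s$X, file.path(dir, xf), row.names = FALSE)
    utils::write.table(s$A_hat, file.path(dir, af), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    data.frame(subject_id = s$subject_id, label = s$label,
               epoch_index = s$epoch_index, x_file = xf, a_file = af)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "samples.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

#' Read model samples written by [write_samples()]
#'
#' @param dir directory containing `samples.csv`.
#' @return list of samples.
#' @export
read_samples <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "samples.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    X <- as.matrix(utils::read.csv(file.path(dir, m$x_file)))
    A <- as.matrix(utils::read.table(file.path(dir, m$a_file), sep = "\t"))
    dimnames(A) <- NULL
    list(X = X, A_hat = A, label = as.integer(m$label),
         subject_id = m$subject_id, epoch_index = m$epoch_index)
  })
}
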