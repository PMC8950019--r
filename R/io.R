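# Trial container IO.
#
# The container is a single JSON document with a hierarchical layout that
# mirrors the channels x samples x trials array convention of epoched EEG:
#   { format, version, fs, role, channel_names,
#     subjects: [ { id, labels: [0/1/-1 per trial],
#                   data: [trial][channel][sample] }, ... ] }
# Labels are encoded as integers in the file: class1 -> 0, class2 -> 1,
# unlabeled -> -1. Numbers are written with 17 significant digits so doubles
# round-trip bit-exactly.

LABEL_CODES <- c(class1 = 0L, class2 = 1L, unlabeled = -1L)

encode_label <- function(label) unname(LABEL_CODES[label])

decode_label <- function(code) {
  idx <- match(as.integer(code), LABEL_CODES)
  if (any(is.na(idx)))
    stop("unknown label code(s) ", paste(unique(code[is.na(idx)]), collapse = ", "),
         "; allowed codes are 0 (class1), 1 (class2), -1 (unlabeled)")
  names(LABEL_CODES)[idx]
}

#' Save a trial set to the single-file JSON container
#'
#' Serializes data, labels, subject partition, sampling rate and channel
#' names losslessly (full double precision). Refuses to clobber an existing
#' file unless `overwrite = TRUE`.
#'
#' @param ts an `mi_trialset`.
#' @param path output file path.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @seealso [load_trialset()]
#' @export
save_trialset <- function(ts, path, overwrite = FALSE) {
  stopifnot(inherits(ts, "mi_trialset"))
  if (file.exists(path) && !overwrite)
    stop("file exists: ", path, " (use overwrite = TRUE to replace it)")
  subj <- subjects_of(ts)
  groups <- split(seq_along(ts$trials), factor(subj, levels = unique(subj)))
  subjects <- lapply(names(groups), function(id) {
    idx <- groups[[id]]
    list(
      id = id,
      labels = vapply(ts$trials[idx], function(t) encode_label(t$label), integer(1)),
      # [trial][channel][sample] nesting in JSON
      data = lapply(ts$trials[idx], function(t)
        lapply(seq_len(nrow(t$data)), function(ch) t$data[ch, ])))
  })
  doc <- list(format = "mitransfer-trialset", version = 1L,
              fs = ts$fs, role = ts$role,
              channel_names = ts$channel_names, subjects = subjects)
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a trial set from disk
#'
#' Reads either the package's JSON container (`format_tag = "container"`) or
#' a directory/collection of plain CSV matrices, one trial per file with rows
#' as channels (`format_tag = "csv_matrix"`, for toy examples).
#'
#' @param path container file, or for `csv_matrix` a character vector of CSV
#'   file paths or a directory containing `*.csv`.
#' @param format_tag `"container"` or `"csv_matrix"`.
#' @param fs sampling rate, required for `csv_matrix` (the CSV carries none).
#' @param labels optional label tokens for `csv_matrix`, one per file.
#' @return An `mi_trialset`.
#' @export
load_trialset <- function(path, format_tag = c("container", "csv_matrix"),
                          fs = NULL, labels = NULL) {
  format_tag <- match.arg(format_tag)
  if (format_tag == "container") return(load_container(path))
  load_csv_matrices(path, fs = fs, labels = labels)
}

load_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mitransfer-trialset"))
    stop("not a mitransfer trial container: ", path)
  channel_names <- unlist(doc$channel_names)
  M <- length(channel_names)
  trials <- list()
  for (s in doc$subjects) {
    labs <- decode_label(unlist(s$labels))
    if (length(s$data) != length(labs))
      stop("subject ", s$id, ": label count does not match trial count")
    for (i in seq_along(s$data)) {
      rows <- s$data[[i]]
      if (length(rows) != M)
        stop(sprintf("subject %s trial %d has %d channels, container declares %d",
                     s$id, i, length(rows), M))
      mat <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
      trials[[length(trials) + 1L]] <-
        trial(mat, label = labs[i], subject = s$id, fs = doc$fs)
    }
  }
  role <- doc$role
  if (is.null(role) || !role %in% c("source", "target", "unassigned"))
    role <- "unassigned"
  trialset(trials, channel_names = channel_names, role = role)
}

load_csv_matrices <- function(path, fs, labels = NULL) {
  if (is.null(fs)) stop("`fs` is required for csv_matrix input")
  files <- path
  if (length(path) == 1L && dir.exists(path))
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no CSV files found at ", paste(path, collapse = ", "))
  if (is.null(labels)) labels <- rep("unlabeled", length(files))
  if (length(labels) != length(files))
    stop("`labels` must have one token per CSV file")
  bad <- setdiff(labels, LABEL_TOKENS)
  if (length(bad) > 0L)
    stop("unknown label token(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(LABEL_TOKENS, collapse = ", "))
  trials <- lapply(seq_along(files), function(i) {
    mat <- as.matrix(utils::read.csv(files[i], header = FALSE))
    storage.mode(mat) <- "double"
    trial(mat, label = labels[i], subject = "s1", fs = fs)
  })
  trialset(trials)
}
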