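# Plain-text interchange: labelled CSV matrices, TSV tables and edge lists.

#' Write / read a labelled connectivity matrix as CSV
#'
#' Header row and index column carry the region labels.
#'
#' @param W a [connectivity_matrix] (or labelled matrix).
#' @param path file path.
#' @return `read_connectivity_csv` returns a [connectivity_matrix];
#'   `write_connectivity_csv` returns `path` invisibly.
#' @export
write_connectivity_csv <- function(W, path) {
  utils::write.csv(as.data.frame(as.matrix(W)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  connectivity_matrix(as.matrix(df), rownames(df))
}

#' Write / read a structural streamline matrix as CSV
#'
#' @param M a [structural_matrix].
#' @param path file path.
#' @return `read_structural_csv` returns a [structural_matrix].
#' @export
write_structural_csv <- function(M, path) {
  utils::write.csv(as.data.frame(as.matrix(M)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_structural_csv
#' @export
read_structural_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  structural_matrix(as.matrix(df), rownames(df))
}

#' Write / read an undirected edge list as 2-column TSV
#'
#' @param edges 2-column matrix of node labels (or indices).
#' @param path file path.
#' @return `read_edge_tsv` returns a 2-column character matrix.
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(as.matrix(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("node_a", "node_b"))
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "character"))
}

#' Persist a simulated cohort to a directory
#'
#' Layout: `subjects.tsv` (subject_id, group, covariate), `planted.tsv`
#' (ground-truth differential edges, two label columns), and
#' `timeseries/<subject>/epoch<k>.csv` (samples x regions, header = region
#' labels) per epoch. Plain-text, loadable with [read_cohort()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  labs <- cohort$layout$region_labels
  write_edge_tsv(cbind(labs[cohort$layout$planted[, 1]],
                       labs[cohort$layout$planted[, 2]]),
                 file.path(dir, "planted.tsv"))
  for (s in seq_along(cohort$ts)) {
    ts <- cohort$ts[[s]]
    sdir <- file.path(dir, "timeseries", ts$subject_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (e in seq_len(dim(ts$data)[1])) {
      ep <- t(ts$data[e, , , drop = TRUE])      # samples x regions
      colnames(ep) <- ts$region_labels
      utils::write.csv(ep, file.path(sdir, sprintf("epoch%03d.csv", e)),
                       row.names = FALSE)
    }
  }
  writeLines(as.character(cohort$ts[[1]]$fs), file.path(dir, "fs.txt"))
  invisible(dir)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir directory containing `subjects.tsv`, `planted.tsv` and
#'   `timeseries/`.
#' @return list with `subjects` (data.frame), `ts` (list of [epoched_ts])
#'   and `planted` (2-column label matrix).
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  planted <- read_edge_tsv(file.path(dir, "planted.tsv"))
  fs <- as.numeric(readLines(file.path(dir, "fs.txt"))[1])
  ts <- lapply(subjects$subject_id, function(id) {
    files <- sort(list.files(file.path(dir, "timeseries", id),
                             pattern = "^epoch.*\\.csv$", full.names = TRUE))
    eps <- lapply(files, function(f) as.matrix(utils::read.csv(f)))
    labs <- colnames(eps[[1]])
    data <- array(0, c(length(eps), ncol(eps[[1]]), nrow(eps[[1]])))
    for (e in seq_along(eps)) data[e, , ] <- t(eps[[e]])
    epoched_ts(data, fs, labs, id)
  })
  list(subjects = subjects, ts = ts, planted = planted)
}

#' Persist a connectivity stack to a directory
#'
#' Layout: `subjects.tsv` (subject_id, group, covariates), `matrices/<id>.csv`
#' (one labelled CSV per subject) and `manifest.tsv` mapping subjects to
#' matrix files.
#'
#' @param stack a [cohort_stack].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "cohort_stack"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  subj <- data.frame(subject_id = stack$subject_id, group = stack$group,
                     stack$covariates, stringsAsFactors = FALSE,
                     check.names = FALSE)
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- sprintf("matrices/%s.csv", stack$subject_id)
  for (s in seq_along(stack$matrices)) {
    write_connectivity_csv(stack$matrices[[s]], file.path(dir, files[s]))
  }
  utils::write.table(data.frame(subject_id = stack$subject_id, file = files),
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a connectivity stack from a directory
#'
#' Reads the layout produced by [write_cohort_stack()].
#'
#' @param dir directory containing `subjects.tsv` and `manifest.tsv`.
#' @return a [cohort_stack].
#' @export
read_cohort_stack <- function(dir) {
  subj <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  mats <- lapply(file.path(dir, man$file), read_connectivity_csv)
  covars <- subj[, setdiff(names(subj), c("subject_id", "group")),
                 drop = FALSE]
  cohort_stack(mats, subj$group, covars, subj$subject_id)
}
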