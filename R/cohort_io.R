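# Plain-text cohort serialization: whitespace-delimited square matrices with
# a label sidecar, a CSV subject table and a JSON ground-truth file.

write_matrix_txt <- function(m, path) {
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), path)
}

read_matrix_txt <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a cohort to a directory
#'
#' Layout: `labels.tsv` (label, hemisphere, cortical sidecar defining row
#' order), one whitespace-delimited matrix file per subject per matrix
#' (`<id>_weights.txt`, `<id>_lengths.txt`), `subjects.csv`,
#' `ground_truth.json` (when present) and `manifest.json`. Round-trips
#' losslessly through [read_cohort()].
#'
#' @param cohort a `synthetic_cohort` (or any list with `connectomes`,
#'   `records`, optionally `ground_truth`).
#' @param directory target directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory ", directory, call. = FALSE)
  ids <- names(cohort$connectomes)
  n <- length(ids)
  if (n > 0) {
    c1 <- cohort$connectomes[[1]]
    utils::write.table(
      data.frame(label = c1$labels, hemisphere = c1$hemisphere,
                 cortical = c1$cortical),
      file.path(directory, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  for (id in ids) {
    write_matrix_txt(cohort$connectomes[[id]]$weights,
                     file.path(directory, paste0(id, "_weights.txt")))
    write_matrix_txt(cohort$connectomes[[id]]$lengths,
                     file.path(directory, paste0(id, "_lengths.txt")))
  }
  utils::write.csv(cohort$records, file.path(directory, "subjects.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth,
                         file.path(directory, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(n_subjects = n, subjects = as.list(ids),
                   files = list(labels = if (n > 0) "labels.tsv" else NULL,
                                subjects = "subjects.csv"))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a cohort from a directory
#'
#' Loads the layout written by [write_cohort()], validating every connectome
#' invariant on load; subjects failing validation are excluded with a warning
#' (the matrix-level analogue of cohort quality control), and their ids and
#' failure reasons are returned in `excluded`.
#'
#' @param directory cohort directory.
#' @return list with `connectomes`, `records`, `ground_truth` (or `NULL`) and
#'   `excluded` (data frame of id + reason).
#' @export
read_cohort <- function(directory) {
  if (!dir.exists(directory))
    stop("cohort directory does not exist: ", directory, call. = FALSE)
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path)) {
    warning("no manifest found in ", directory, ": returning empty cohort",
            call. = FALSE)
    return(list(connectomes = list(), records = NULL, ground_truth = NULL,
                excluded = data.frame(id = character(0),
                                      reason = character(0))))
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  ids <- as.character(manifest$subjects)
  records <- NULL
  sub_path <- file.path(directory, "subjects.csv")
  if (file.exists(sub_path))
    records <- utils::read.csv(sub_path, stringsAsFactors = FALSE)
  gt <- NULL
  gt_path <- file.path(directory, "ground_truth.json")
  if (file.exists(gt_path))
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  connectomes <- list()
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (length(ids) > 0) {
    labels <- utils::read.table(file.path(directory, "labels.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    for (id in ids) {
      res <- tryCatch({
        w <- read_matrix_txt(file.path(directory, paste0(id, "_weights.txt")))
        len <- read_matrix_txt(file.path(directory,
                                         paste0(id, "_lengths.txt")))
        obj <- connectome(w, len, labels$label, labels$hemisphere,
                          labels$cortical, validate = FALSE)
        problems <- validate_connectome(obj)
        if (length(problems) > 0) stop(paste(problems, collapse = "; "))
        obj
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        excluded <- rbind(excluded, data.frame(id = id, reason = res,
                                               stringsAsFactors = FALSE))
      } else {
        connectomes[[id]] <- res
      }
    }
    if (nrow(excluded) > 0) {
      warning(nrow(excluded), " subject(s) failed validation and were ",
              "excluded: ", paste(excluded$id, collapse = ", "),
              call. = FALSE)
      if (!is.null(records))
        records <- records[records$id %in% names(connectomes), ]
    }
  }
  list(connectomes = connectomes, records = records, ground_truth = gt,
       excluded = excluded)
}
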