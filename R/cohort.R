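#' Stack subject matrices into a cohort tensor
#'
#' Builds the n x p x p array whose first (sample) mode indexes subjects, with
#' phenotype records aligned to the slices. All matrices must share the node
#' count p and the phenotype table must have one row per matrix.
#'
#' @param matrices List of p x p matrices, one per subject, in cohort order.
#' @param phenotypes Data frame with columns `subject_id`, `label` (one of
#'   `"AD"`, `"MCI"`, `"NC"`), `age` (years, positive) and `sex`
#'   (`"M"`/`"F"`).
#' @return A `cohort_tensor`: list with `data` (n x p x p array) and
#'   `phenotypes`.
#' @export
stack_cohort <- function(matrices, phenotypes) {
  n <- length(matrices)
  if (n == 0L) stop("no matrices supplied")
  phenotypes <- validate_phenotypes(phenotypes)
  if (nrow(phenotypes) != n) {
    stop(sprintf("%d matrices but %d phenotype rows", n, nrow(phenotypes)))
  }
  p <- nrow(matrices[[1]])
  dims <- vapply(matrices, function(m) c(nrow(m), ncol(m)), integer(2))
  if (any(dims != p)) {
    stop(sprintf("all matrices must be %d x %d; subject %d is %d x %d",
                 p, p, which(dims[1, ] != p | dims[2, ] != p)[1L],
                 dims[1, which(dims[1, ] != p | dims[2, ] != p)[1L]],
                 dims[2, which(dims[1, ] != p | dims[2, ] != p)[1L]]))
  }
  data <- array(0, dim = c(n, p, p))
  for (i in seq_len(n)) data[i, , ] <- as.matrix(matrices[[i]])
  structure(list(data = data, phenotypes = phenotypes),
            class = "cohort_tensor")
}

validate_phenotypes <- function(phenotypes) {
  phenotypes <- as.data.frame(phenotypes)
  needed <- c("subject_id", "label", "age", "sex")
  missing <- setdiff(needed, names(phenotypes))
  if (length(missing)) {
    stop("phenotype table lacks column(s): ", paste(missing, collapse = ", "))
  }
  phenotypes$label <- as.character(phenotypes$label)
  if (!all(phenotypes$label %in% c("AD", "MCI", "NC"))) {
    stop("labels must be AD, MCI or NC")
  }
  if (any(!is.finite(phenotypes$age)) || any(phenotypes$age <= 0)) {
    stop("ages must be positive and finite")
  }
  phenotypes$sex <- as.character(phenotypes$sex)
  if (!all(phenotypes$sex %in% c("M", "F"))) stop("sex must be M or F")
  phenotypes
}

#' @export
print.cohort_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Cohort tensor: %d subjects x %d x %d nodes\n", d[1], d[2], d[3]))
  cat("Groups:", paste(sprintf("%s=%d", names(table(x$phenotypes$label)),
                               table(x$phenotypes$label)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of subjects and nodes of a cohort tensor
#' @param x A `cohort_tensor`.
#' @return Integer vector `(n, p, p)`.
#' @export
dim.cohort_tensor <- function(x) dim(x$data)

#' Write a cohort as a directory of matrix files plus a phenotype CSV
#'
#' Serializes each subject's slice as `<subject_id>.txt` (space-delimited) and
#' the phenotype table as `phenotypes.csv` in `dir`.
#'
#' @param cohort A `cohort_tensor`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ph <- cohort$phenotypes
  for (i in seq_len(nrow(ph))) {
    write_connectivity_matrix(cohort$data[i, , ],
                              file.path(dir, paste0(ph$subject_id[i], ".txt")))
  }
  utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory holding `phenotypes.csv` and one matrix file per
#'   subject named `<subject_id>.txt`.
#' @return A `cohort_tensor`.
#' @export
read_cohort <- function(dir) {
  ph <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                        stringsAsFactors = FALSE)
  mats <- lapply(ph$subject_id, function(id) {
    read_connectivity_matrix(file.path(dir, paste0(id, ".txt")))
  })
  stack_cohort(mats, ph)
}
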