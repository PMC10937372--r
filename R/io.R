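#' Read and write the pipeline's tabular interchange formats
#'
#' Study summaries travel as tab-delimited text with header columns
#' `CHR POS EA NEA EAF BETA SE N_CASE N_CONTROL INFO` (one file per study);
#' annotations as BED (0-based, half-open, 4th column = class); z-score
#' matrices as tab-delimited with explicit `NA` tokens; cohort dosages as a
#' dense tab-delimited matrix with a sample-metadata sidecar.
#'
#' @param study_set An `mx_study_set`.
#' @param dir Output directory (created if needed).
#' @return `write_study_summaries()` invisibly returns the written file
#'   paths; `read_study_summaries()` returns a long summary tibble plus a
#'   `studies` attribute with the metadata sidecar.
#' @name study_io
NULL

#' @rdname study_io
#' @export
write_study_summaries <- function(study_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- study_set$summaries %>%
    dplyr::group_by(.data$study) %>%
    dplyr::group_map(function(df, key) {
      path <- file.path(dir, paste0(key$study, ".tsv"))
      out <- df %>%
        dplyr::transmute(
          CHR = .data$chr, POS = .data$pos, SNV = .data$snv,
          EA = .data$ea, NEA = .data$nea, EAF = .data$eaf,
          BETA = .data$beta, SE = .data$se,
          N_CASE = .data$n_case, N_CONTROL = .data$n_control,
          INFO = .data$info
        )
      readr::write_tsv(out, path)
      path
    })
  readr::write_tsv(study_set$studies, file.path(dir, "studies.tsv"))
  invisible(unlist(paths))
}

#' @rdname study_io
#' @export
read_study_summaries <- function(dir) {
  meta <- readr::read_tsv(file.path(dir, "studies.tsv"),
                          show_col_types = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.tsv$", full.names = TRUE),
                   file.path(dir, "studies.tsv"))
  summ <- purrr::map_dfr(files, function(f) {
    study <- sub("\\.tsv$", "", basename(f))
    readr::read_tsv(f, show_col_types = FALSE) %>%
      dplyr::transmute(
        study = study,
        ancestry = meta$ancestry[match(study, meta$study)],
        snv = .data$SNV, chr = .data$CHR, pos = .data$POS,
        ea = .data$EA, nea = .data$NEA, eaf = .data$EAF,
        beta = .data$BETA, se = .data$SE,
        n_case = .data$N_CASE, n_control = .data$N_CONTROL,
        info = .data$INFO
      )
  })
  structure(list(summaries = summ, studies = meta,
                 truth = NULL), class = "mx_study_set")
}

#' Write/read annotation intervals as BED
#'
#' BED is 0-based, half-open; the 4th column carries the annotation class
#' or cell-type name.
#'
#' @param annotations An `mx_annotation_set` or interval tibble (chr,
#'   start, end, class).
#' @param path File path.
#' @return `read_bed()` returns an interval tibble.
#' @export
write_bed <- function(annotations, path) {
  iv <- if (inherits(annotations, "mx_annotation_set")) annotations$intervals else annotations
  readr::write_tsv(iv[, c("chr", "start", "end", "class")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chr", "start", "end", "class"),
                  col_types = "ciic")
}

#' Write/read a z-score matrix with explicit NA tokens
#'
#' @param Z An `mx_zmatrix` (or plain matrix).
#' @param path File path.
#' @export
write_zmatrix <- function(Z, path) {
  df <- tibble::as_tibble(unclass(Z), rownames = "snv")
  readr::write_tsv(df, path, na = "NA")
  n_phen <- attr(Z, "n_phen")
  if (!is.null(n_phen)) {
    readr::write_tsv(tibble::tibble(phenotype = names(n_phen), n = n_phen),
                     paste0(path, ".n"))
  }
  invisible(path)
}

#' @rdname write_zmatrix
#' @export
read_zmatrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  Z <- as.matrix(df[, -1])
  rownames(Z) <- df$snv
  npath <- paste0(path, ".n")
  n_phen <- NULL
  if (file.exists(npath)) {
    nd <- readr::read_tsv(npath, show_col_types = FALSE)
    n_phen <- setNames(nd$n, nd$phenotype)
  }
  structure(Z, class = c("mx_zmatrix", "matrix", "array"), n_phen = n_phen)
}
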