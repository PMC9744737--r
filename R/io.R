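#' @importFrom utils read.delim write.table
#' @importFrom stats complete.cases
NULL

# Detect tab vs comma delimiter from the header line of a file.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  sep <- detect_sep(path)
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read an analyte panel file
#'
#' The panel is a wide delimited table: first column `sample_id`, remaining
#' columns one analyte each, values in relative fluorescence units (RFU).
#' Values are carried internally as natural-log RFU; with
#' `log_transform = TRUE` the file holds raw RFU (all strictly positive) and
#' `log()` is applied on load.
#'
#' @param path file path (TSV or CSV, delimiter auto-detected).
#' @param log_transform apply the natural log on load.
#' @return Numeric matrix, samples in rows (rownames = sample IDs),
#'   analytes in columns.
#' @export
read_panel <- function(path, log_transform = FALSE) {
  df <- read_delim_auto(path)
  if (names(df)[1] != "sample_id") {
    stop("panel file must have 'sample_id' as its first column, found '",
         names(df)[1], "'")
  }
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample IDs in panel: ", paste(dup, collapse = ", "))
  }
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  if (anyDuplicated(colnames(x))) {
    stop("duplicate analyte IDs in panel: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyNA(x)) stop("panel contains missing values; imputation is not supported")
  if (log_transform) {
    if (any(x <= 0)) {
      bad <- which(x <= 0, arr.ind = TRUE)[1, ]
      stop("raw-RFU panel contains non-positive value at sample '",
           rownames(x)[bad[1]], "', analyte '", colnames(x)[bad[2]],
           "'; the natural-log transform requires strictly positive RFU")
    }
    x <- log(x)
  }
  x
}

#' Read the sample metadata table
#'
#' @param path file path. Required columns: `sample_id`, `subject_id`,
#'   `cohort` (HV/MS), `subtype` (HV/RRMS/SPMS/PPMS), `age`, `sex` (F/M),
#'   `visit_index`. Optional outcome columns (e.g. `msdss_baseline`,
#'   `msdss_followup`, `armss`, `msss`, `edss`, `bpfr`, `progression_slope`,
#'   `snfl`, `cnfl`) are kept as supplied.
#' @return A data.frame with `sex_f` added (indicator, female = 1).
#' @export
read_metadata <- function(path) {
  md <- read_delim_auto(path)
  required <- c("sample_id", "subject_id", "cohort", "subtype", "age", "sex",
                "visit_index")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop("metadata is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  md$sample_id <- as.character(md$sample_id)
  dup <- unique(md$sample_id[duplicated(md$sample_id)])
  if (length(dup)) stop("duplicate sample IDs in metadata: ",
                        paste(dup, collapse = ", "))
  if (!all(md$cohort %in% c("HV", "MS"))) {
    stop("unknown cohort codes: ",
         paste(unique(setdiff(md$cohort, c("HV", "MS"))), collapse = ", "))
  }
  if (!all(md$sex %in% c("F", "M"))) {
    stop("unknown sex codes (expected F/M): ",
         paste(unique(setdiff(md$sex, c("F", "M"))), collapse = ", "))
  }
  md$sex_f <- as.numeric(md$sex == "F")
  md
}

#' Read the external serum reference coefficient table
#'
#' Emulates a published healthy-donor serum study: per analyte and covariate
#' (age or sex), the reported coefficient and whether the association was
#' significant there. Only significant rows anchor the tier-1 screen.
#'
#' @param path file path with columns `analyte_id`, `covariate`,
#'   `coefficient`, `significant`.
#' @return A data.frame with `direction` (+1/-1) added.
#' @export
read_reference <- function(path) {
  ref <- read_delim_auto(path)
  required <- c("analyte_id", "covariate", "coefficient", "significant")
  missing <- setdiff(required, names(ref))
  if (length(missing)) {
    stop("reference table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!all(ref$covariate %in% c("age", "sex"))) {
    stop("reference covariate must be 'age' or 'sex'")
  }
  ref$significant <- as.logical(ref$significant)
  ref$direction <- sign(ref$coefficient)
  ref
}

#' Read all pipeline inputs
#'
#' Loads panel, metadata and reference table per the configuration, aligns
#' the metadata rows to the panel sample order, and logs a load report.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `panel` (log-RFU matrix), `metadata`,
#'   `reference`.
#' @export
read_inputs <- function(config) {
  panel <- read_panel(config$panel_path, log_transform = config$log_transform)
  metadata <- read_metadata(config$metadata_path)
  reference <- read_reference(config$reference_path)
  missing <- setdiff(rownames(panel), metadata$sample_id)
  if (length(missing)) {
    stop("panel samples absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, rownames(panel))
  if (length(extra)) {
    stop("metadata samples absent from panel: ", paste(extra, collapse = ", "))
  }
  metadata <- metadata[match(rownames(panel), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  message(sprintf(
    "loaded %d samples x %d analytes (%d HV, %d MS); reference rows: %d",
    nrow(panel), ncol(panel), sum(metadata$cohort == "HV"),
    sum(metadata$cohort == "MS"), nrow(reference)))
  list(panel = panel, metadata = metadata, reference = reference)
}

#' Write a numeric table losslessly
#'
#' Tab-separated, 17 significant digits, so that a read/write round trip
#' reproduces doubles to within 1e-12.
#'
#' @param df data.frame to write.
#' @param path destination path.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a panel matrix as a TSV with a sample_id column
#' @param panel samples x analytes matrix with rownames.
#' @param path destination path.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(sample_id = rownames(panel), as.data.frame(panel),
                   check.names = FALSE)
  write_tsv(df, path)
}

# Hash of the configuration: md5 of its canonical JSON rendering.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[sort(names(config))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write the results bundle and manifest
#'
#' Writes every populated result component to `outdir` as a deterministic
#' file set, plus a `manifest.json` listing the files, the configuration
#' hash and the master seed. Re-running with identical inputs and seed
#' reproduces byte-identical numeric tables.
#'
#' @param results named list; recognised elements: `adjusted_panel` (matrix),
#'   `metrics` (list, written as JSON), any data.frame (written as TSV named
#'   after the element).
#' @param outdir output directory, created if needed.
#' @param config the [pipeline_config()] of the run.
#' @return Invisibly, the manifest as a list.
#' @export
write_results_bundle <- function(results, outdir, config) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character(0)
  for (name in names(results)) {
    obj <- results[[name]]
    if (is.null(obj)) next
    if (name == "adjusted_panel" || (is.matrix(obj) && !is.null(rownames(obj)))) {
      f <- file.path(outdir, paste0(name, ".tsv"))
      write_panel(obj, f)
    } else if (is.data.frame(obj)) {
      f <- file.path(outdir, paste0(name, ".tsv"))
      write_tsv(obj, f)
    } else {
      f <- file.path(outdir, paste0(name, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    files <- c(files, basename(f))
  }
  manifest <- list(files = files, config_hash = config_hash(config),
                   seed = config$seed,
                   sex_reference_level = "M (indicator sex_f = 1 for F)")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
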