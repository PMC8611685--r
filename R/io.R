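# Canonical DVH exchange format (CSV):
#   # structure: <name>
#   # total_volume_cc: <float>
#   # dose_unit: Gy
#   dose,volume_fraction
#   <dose>,<fraction>        (ascending dose, 6 significant digits)

#' Write a cumulative DVH in the canonical CSV dialect
#'
#' Values are written at 6 significant digits; [read_dvh_file()] followed by
#' another write reproduces the file byte-identically.
#'
#' @param dvh a [cumulative_dvh()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_dvh_file <- function(dvh, path) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  lines <- c(
    sprintf("# structure: %s", dvh$structure),
    sprintf("# total_volume_cc: %s", format_sig6(dvh$total_volume_cc)),
    "# dose_unit: Gy",
    "dose,volume_fraction",
    sprintf("%s,%s", format_sig6(dvh$dose_edges),
            format_sig6(dvh$volume_fraction)))
  writeLines(lines, path)
  invisible(path)
}

format_sig6 <- function(x) sprintf("%.6g", x)

#' Read a cumulative DVH from the canonical CSV dialect
#'
#' Violations of the DVH invariants (non-monotone curve, non-ascending dose
#' axis, malformed rows) are rejected at read time with the offending line
#' number.
#'
#' @param path file path.
#' @return A [cumulative_dvh()].
#' @export
read_dvh_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L) stop("truncated DVH file: ", path, call. = FALSE)
  header <- function(i, key) {
    pat <- paste0("^# ", key, ": *")
    if (!grepl(pat, lines[i]))
      stop(sprintf("malformed DVH header at line %d (expected '# %s: ...')",
                   i, key), call. = FALSE)
    sub(pat, "", lines[i])
  }
  structure_name <- header(1L, "structure")
  total_volume <- suppressWarnings(as.numeric(header(2L, "total_volume_cc")))
  if (is.na(total_volume))
    stop("malformed DVH header at line 2 (total_volume_cc not numeric)",
         call. = FALSE)
  unit <- header(3L, "dose_unit")
  if (unit != "Gy")
    stop("unsupported dose unit at line 3: ", unit, call. = FALSE)
  if (lines[4L] != "dose,volume_fraction")
    stop("malformed DVH column header at line 4", call. = FALSE)
  rows <- lines[-(1:4)]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed DVH row at line %d", bad[1L] + 4L), call. = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2L,
                byrow = TRUE)
  bad <- which(!stats::complete.cases(mat))
  if (length(bad))
    stop(sprintf("non-numeric DVH row at line %d", bad[1L] + 4L), call. = FALSE)
  d <- mat[, 1L]; vf <- mat[, 2L]
  bad <- which(diff(d) <= 0)
  if (length(bad))
    stop(sprintf("non-ascending dose at line %d", bad[1L] + 5L), call. = FALSE)
  bad <- which(diff(vf) > 1e-12)
  if (length(bad))
    stop(sprintf("non-monotone DVH at line %d", bad[1L] + 5L), call. = FALSE)
  cumulative_dvh(d, vf, total_volume, structure_name)
}

# Plain-text grid container ----------------------------------------------
# Runtime exchange format for dose grids and masks produced by the
# synthetic module (one value per line after a 4-line header). Full
# double precision (%.17g) so metrics computed from re-read grids match
# in-memory results exactly.

#' Write a dose grid or structure mask as a plain-text container
#'
#' @param x a [dose_grid()] or [structure_mask()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_grid_file <- function(x, path) {
  kind <- if (inherits(x, "dose_grid")) "dose_grid" else if
    (inherits(x, "structure_mask")) "structure_mask" else
      stop("x must be a dose_grid or structure_mask", call. = FALSE)
  vals <- if (kind == "dose_grid") sprintf("%.17g", x$values)
          else as.character(as.integer(x$values))
  name <- if (kind == "structure_mask") x$name else "dose"
  lines <- c(
    sprintf("# sbrtTCP %s v1: %s", kind, name),
    sprintf("# shape_zyx: %s", paste(dim(x$values), collapse = " ")),
    sprintf("# spacing_mm: %s", paste(sprintf("%.17g", x$spacing_mm),
                                      collapse = " ")),
    sprintf("# origin_mm: %s", paste(sprintf("%.17g", x$origin_mm),
                                     collapse = " ")),
    vals)
  writeLines(lines, path)
  invisible(path)
}

#' Read a dose grid or structure mask from the plain-text container
#'
#' @param path file path.
#' @return A [dose_grid()] or [structure_mask()], matching what was written.
#' @export
read_grid_file <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  head4 <- readLines(con, n = 4L)
  m <- regmatches(head4[1L],
                  regexec("^# sbrtTCP (dose_grid|structure_mask) v1: (.*)$",
                          head4[1L]))[[1L]]
  if (length(m) != 3L) stop("not a grid container: ", path, call. = FALSE)
  kind <- m[2L]; name <- m[3L]
  shape <- as.integer(strsplit(sub("^# shape_zyx: ", "", head4[2L]), " ")[[1L]])
  spacing <- as.numeric(strsplit(sub("^# spacing_mm: ", "", head4[3L]), " ")[[1L]])
  origin <- as.numeric(strsplit(sub("^# origin_mm: ", "", head4[4L]), " ")[[1L]])
  if (length(shape) != 3L || anyNA(shape))
    stop("malformed grid header: ", path, call. = FALSE)
  vals <- scan(con, what = double(), n = prod(shape), quiet = TRUE)
  if (length(vals) != prod(shape))
    stop("grid container truncated: ", path, call. = FALSE)
  arr <- array(vals, shape)
  if (kind == "dose_grid") dose_grid(arr, spacing, origin)
  else structure_mask(name, array(arr != 0, shape), spacing, origin)
}

# Cohort directory layout -------------------------------------------------

#' Export a synthetic cohort to a directory tree
#'
#' Writes one sub-directory per patient containing the three dose grids
#' (`dose_AAA.txt`, `dose_AXB_Dm.txt`, `dose_AXB_Dw.txt`), the target and
#' lung masks, and a JSON manifest (prescription, seed, achieved lung
#' fraction).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    pd <- file.path(dir, p$patient_id)
    dir.create(pd, showWarnings = FALSE)
    for (arm in names(p$doses))
      write_grid_file(p$doses[[arm]], file.path(pd, sprintf("dose_%s.txt", arm)))
    write_grid_file(p$phantom$ptv_mask, file.path(pd, "mask_PTV.txt"))
    write_grid_file(p$phantom$lung_mask, file.path(pd, "mask_Lung.txt"))
    manifest <- list(patient_id = p$patient_id,
                     prescription_gy = p$prescription_gy,
                     achieved_lung_fraction = p$achieved_lung_fraction,
                     seed = p$seed)
    jsonlite::write_json(manifest, file.path(pd, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort_dir()]
#'
#' @param dir cohort directory.
#' @return A list shaped like a [simulate_cohort()] result (phantom masks,
#'   per-arm dose grids, manifest fields).
#' @export
read_cohort_dir <- function(dir) {
  pds <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(pds)) stop("no patient directories under ", dir, call. = FALSE)
  patients <- lapply(pds, function(pd) {
    manifest <- jsonlite::read_json(file.path(pd, "manifest.json"),
                                    simplifyVector = TRUE)
    doses <- lapply(c(AAA = "AAA", AXB_Dm = "AXB_Dm", AXB_Dw = "AXB_Dw"),
                    function(arm)
                      read_grid_file(file.path(pd, sprintf("dose_%s.txt", arm))))
    list(patient_id = manifest$patient_id,
         phantom = list(ptv_mask = read_grid_file(file.path(pd, "mask_PTV.txt")),
                        lung_mask = read_grid_file(file.path(pd, "mask_Lung.txt"))),
         prescription_gy = manifest$prescription_gy,
         doses = doses,
         achieved_lung_fraction = manifest$achieved_lung_fraction,
         seed = manifest$seed)
  })
  structure(patients, class = "synthetic_cohort")
}

# Cohort records CSV -------------------------------------------------------

#' Write/read long-format cohort records as a flat CSV
#'
#' Columns: `patient_id, region, metric, arm, value`. Values carry full
#' precision (`%.17g`) so that pipeline stages composed through files give
#' byte-identical reports to the in-memory pipeline.
#'
#' @param records a [cohort_records()] `data.frame`.
#' @param path file path.
#' @return `path` (write) or the records `data.frame` (read).
#' @export
write_records_csv <- function(records, path) {
  lines <- c("patient_id,region,metric,arm,value",
             sprintf("%s,%s,%s,%s,%.17g", records$patient_id, records$region,
                     records$metric, records$arm, records$value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  need <- c("patient_id", "region", "metric", "arm", "value")
  if (!all(need %in% names(df)))
    stop("records CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cohort_records(df$patient_id, df$region, df$metric, df$arm, df$value)
}
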