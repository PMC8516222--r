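# Readers and writers for the pipeline's exchange formats: PLINK
# .bed/.bim/.fam (variant-major v1.00), dosage CSV, weather CSV,
# coordinate CSVs, exposure CSV, dense GRM with id sidecar, JSON reports.

# ---- PLINK binary triple ---------------------------------------------------

# two-bit PLINK codes (variant-major): 00 = hom alt (dose 2 of A1... we
# adopt the usual convention of counting the A1 allele), 01 = missing,
# 10 = het, 11 = hom ref. We count the A1 allele: 00 -> 2, 10 -> 1, 11 -> 0.
PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write genotypes as a PLINK .bed/.bim/.fam triple
#'
#' Variant-major v1.00 binary layout with the standard magic bytes
#' `6C 1B 01`. Doses count the A1 allele; fractional (imputed) doses are
#' not representable and raise an error.
#'
#' @param geno A `genotype_matrix` with integer doses or `NA`.
#' @param prefix Path prefix; writes `<prefix>.bed`, `.bim`, `.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  doses <- geno$doses
  if (any(!is.na(doses) & doses != round(doses))) {
    stop("PLINK .bed cannot store fractional doses")
  }
  map <- geno$map
  a1 <- if ("a1" %in% names(map)) map$a1 else rep("A", nrow(map))
  a2 <- if ("a2" %in% names(map)) map$a2 else rep("B", nrow(map))
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$pos_bp, a1, a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$animal_ids, geno$animal_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  n <- nrow(doses)
  code <- matrix(0x01, nrow = n, ncol = ncol(doses)) # default: missing
  code[!is.na(doses) & doses == 2] <- 0x00
  code[!is.na(doses) & doses == 1] <- 0x02
  code[!is.na(doses) & doses == 0] <- 0x03
  pad <- (4 - n %% 4) %% 4
  if (pad > 0) code <- rbind(code, matrix(0x00, pad, ncol(doses)))
  idx <- seq(1, nrow(code), by = 4)
  packed <- code[idx, , drop = FALSE] +
    4 * code[idx + 1, , drop = FALSE] +
    16 * code[idx + 2, , drop = FALSE] +
    64 * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam triple
#'
#' @param prefix Path prefix of the triple.
#' @return A `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chr", "snp_id", "cm", "pos_bp",
                                         "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, PLINK_MAGIC)) {
    stop("not a variant-major PLINK v1.00 .bed file (bad magic bytes)")
  }
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) != bytes_per_snp * m) stop("truncated .bed file")
  vals <- as.integer(raw)
  two_bits <- cbind(vals %% 4, (vals %/% 4) %% 4,
                    (vals %/% 16) %% 4, (vals %/% 64) %% 4)
  codes <- matrix(t(two_bits), nrow = bytes_per_snp * 4)[seq_len(n), ,
                                                         drop = FALSE]
  dim(codes) <- c(n, m)
  doses <- matrix(NA_real_, n, m)
  doses[codes == 0x00] <- 2
  doses[codes == 0x02] <- 1
  doses[codes == 0x03] <- 0
  genotype_matrix(doses, bim[, c("snp_id", "chr", "pos_bp", "a1", "a2")],
                  animal_ids = fam[[1]])
}

# ---- plain-text tables -----------------------------------------------------

#' Write genotypes as a dosage CSV
#'
#' First column `animal_id`, one column per SNP (header = snp id), missing
#' doses empty. A `<path>.map.csv` sidecar stores the marker map.
#' @param geno A `genotype_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(geno, path) {
  df <- data.frame(animal_id = geno$animal_ids, geno$doses,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(geno$map, paste0(path, ".map.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a dosage CSV (with its `.map.csv` sidecar)
#' @param path CSV path written by [write_dosage_csv()].
#' @return A `genotype_matrix`.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = "")
  map <- utils::read.csv(paste0(path, ".map.csv"), stringsAsFactors = FALSE)
  doses <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(doses) <- "numeric")
  bad <- which(!is.na(df[, -1, drop = FALSE]) & is.na(doses) |
                 (!is.na(doses) & !(doses %in% c(0, 1, 2))), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("bad dose code at row %d, column '%s'",
                 bad[1, 1], colnames(doses)[bad[1, 2]]))
  }
  genotype_matrix(doses, map, animal_ids = df[[1]])
}

#' Write/read the weather CSV (station_id, timestamp, temp_c, rh_pct)
#' @param weather Weather data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_weather_csv <- function(weather, path) {
  out <- weather
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  if (anyNA(df$timestamp)) stop("unparseable timestamps in ", path)
  df
}

#' Write/read the exposure CSV (animal_id, week, weekly_thi, hs_flag)
#' @param exposure Exposure table.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_exposure_csv <- function(exposure, path) {
  utils::write.csv(exposure, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "week", "weekly_thi", "hs_flag") %in% names(df)))
  if (!all(df$hs_flag == as.integer(df$weekly_thi >= 60))) {
    stop("exposure file violates the hs_flag = [weekly_thi >= 60] invariant")
  }
  df
}

#' Write/read a dense GRM as TSV with an id sidecar
#' @param grm A `grm`.
#' @param path TSV path; ids go to `<path>.ids`.
#' @return `path` (write) or a `grm` (read).
#' @export
write_grm <- function(grm, path) {
  utils::write.table(grm$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  writeLines(grm$animal_ids, paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(values) <- NULL
  ids <- readLines(paste0(path, ".ids"))
  structure(list(values = values, animal_ids = ids,
                 denominator = NA_real_, kind = "G"), class = "grm")
}
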