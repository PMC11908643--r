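## Reading/writing genotype and phenotype files, alignment, outer splitting.

#' Construct a GenotypeMatrix from a dosage matrix
#'
#' Checks shape, imputes missing entries (NA or -9) by the per-marker mean of
#' the observed dosages, and flags zero-variance markers. Non-missing entries
#' are never altered.
#'
#' @param dosages numeric matrix, individuals x markers.
#' @param sampleIds,markerIds identifier vectors; default from dimnames or
#'   generated.
#' @return A [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosages,
                           sampleIds = rownames(dosages),
                           markerIds = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (is.null(markerIds)) markerIds <- sprintf("M%05d", seq_len(ncol(dosages)))
  dosages[dosages == -9] <- NA_real_
  if (anyNA(dosages)) {
    for (j in which(colSums(is.na(dosages)) > 0L)) {
      obs <- dosages[, j][!is.na(dosages[, j])]
      if (length(obs) == 0L)
        stop(sprintf("marker '%s' has no observed dosages to impute from",
                     markerIds[j]), call. = FALSE)
      dosages[is.na(dosages[, j]), j] <- mean(obs)
    }
  }
  mono <- apply(dosages, 2L, function(v) max(v) - min(v) == 0)
  dimnames(dosages) <- NULL
  new("GenotypeMatrix", sampleIds = as.character(sampleIds),
      markerIds = as.character(markerIds), dosages = dosages,
      monomorphic = as.logical(mono))
}

#' Construct a PhenotypeVector
#'
#' @param values numeric trait values.
#' @param sampleIds identifiers, one per value.
#' @param traitName trait label.
#' @param nDropped individuals removed for missing phenotype (bookkeeping).
#' @return A [PhenotypeVector-class].
#' @export
phenotypeVector <- function(values, sampleIds = names(values),
                            traitName = "trait", nDropped = 0L) {
  if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_along(values))
  new("PhenotypeVector", sampleIds = as.character(sampleIds),
      values = as.numeric(values), traitName = traitName,
      nDropped = as.integer(nDropped))
}

.checkNumericColumns <- function(dt, cols, path) {
  for (nm in cols) {
    v <- dt[[nm]]
    if (is.character(v)) {
      vt <- trimws(v)
      conv <- suppressWarnings(as.numeric(vt))
      bad <- which(is.na(conv) & !(vt %in% c("NA", "", "nan", "NaN")))
      if (length(bad))
        stop(sprintf(
          "non-numeric dosage/phenotype value '%s' in column '%s' of '%s' (data line %d)",
          v[bad[1L]], nm, path, bad[1L]), call. = FALSE)
      data.table::set(dt, j = nm, value = conv)
    } else if (!is.numeric(v) && !is.logical(v)) {
      stop(sprintf("column '%s' of '%s' is not numeric", nm, path),
           call. = FALSE)
    }
  }
  dt
}

#' Read a genotype dosage file
#'
#' Two dialects are supported. `csv`: a header row of marker IDs with the
#' first column holding sample IDs. `plink_raw`: the whitespace-delimited
#' additive-coding export of `plink --recode A`, with leading columns
#' FID IID PAT MAT SEX PHENOTYPE followed by one dosage column per SNP;
#' sample IDs are taken from IID.
#'
#' Missing dosages (NA or -9) are imputed with the per-marker mean of the
#' observed values; markers with zero variance after imputation are retained
#' but flagged (see [monomorphicMarkers()]).
#'
#' @param path file path.
#' @param format `"csv"` or `"plink_raw"`.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("csv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = TRUE,
                      na.strings = c("NA", "")),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (format == "csv") {
    if (ncol(dt) < 2L)
      stop(sprintf("'%s': need a sample-ID column plus at least one marker", path),
           call. = FALSE)
    ids <- as.character(dt[[1L]])
    markers <- names(dt)[-1L]
    dt <- .checkNumericColumns(dt, markers, path)
    mat <- as.matrix(dt[, markers, with = FALSE])
  } else {
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(dt) < 7L || !all(lead %in% names(dt)[1:6]))
      stop(sprintf(
        "'%s' does not look like a plink .raw file (expected leading columns %s)",
        path, paste(lead, collapse = " ")), call. = FALSE)
    ids <- as.character(dt[["IID"]])
    markers <- setdiff(names(dt), lead)
    dt <- .checkNumericColumns(dt, markers, path)
    mat <- as.matrix(dt[, markers, with = FALSE])
  }
  rownames(mat) <- ids
  genotypeMatrix(mat, sampleIds = ids, markerIds = markers)
}

#' Write a GenotypeMatrix as CSV
#'
#' Inverse of [readGenotypes()] with `format = "csv"`: header of marker IDs,
#' first column `sample_id`. Round-trips dosages exactly.
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(G, path) {
  dt <- data.table::data.table(sample_id = sampleIds(G))
  d <- G@dosages
  for (j in seq_along(G@markerIds))
    data.table::set(dt, j = G@markerIds[j], value = d[, j])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a phenotype table and extract one trait
#'
#' Expects a TSV whose first column holds sample IDs and whose remaining
#' named columns hold numeric traits. Individuals with a missing value for
#' the requested trait are dropped (their count is recorded in the returned
#' object and reported via a message).
#'
#' @param path file path.
#' @param trait trait column name.
#' @return A [PhenotypeVector-class].
#' @export
readPhenotypes <- function(path, trait) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = TRUE, sep = "\t",
                      na.strings = c("NA", "")),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (ncol(dt) < 2L)
    stop(sprintf("'%s': need a sample-ID column plus at least one trait", path),
         call. = FALSE)
  traits <- names(dt)[-1L]
  if (!trait %in% traits)
    stop(sprintf("trait '%s' not found in '%s'; available traits: %s",
                 trait, path, paste(traits, collapse = ", ")), call. = FALSE)
  dt <- .checkNumericColumns(dt, trait, path)
  ids <- as.character(dt[[1L]])
  v <- dt[[trait]]
  keep <- !is.na(v)
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    message(sprintf("dropped %d individual(s) with missing '%s'", nDropped, trait))
  phenotypeVector(v[keep], sampleIds = ids[keep], traitName = trait,
                  nDropped = nDropped)
}

#' Align a genotype matrix and a phenotype vector by sample ID
#'
#' Restricts both objects to the intersection of their sample IDs, in
#' genotype-file order.
#'
#' @param G a [GenotypeMatrix-class].
#' @param y a [PhenotypeVector-class].
#' @return A list with elements `G` and `y`, row-aligned.
#' @export
alignData <- function(G, y) {
  common <- intersect(sampleIds(G), sampleIds(y))
  if (length(common) < 2L)
    stop(sprintf("only %d sample ID(s) shared between genotypes and phenotypes",
                 length(common)), call. = FALSE)
  gi <- match(common, sampleIds(G))
  yi <- match(common, sampleIds(y))
  G2 <- new("GenotypeMatrix", sampleIds = G@sampleIds[gi],
            markerIds = G@markerIds, dosages = G@dosages[gi, , drop = FALSE],
            monomorphic = G@monomorphic)
  y2 <- new("PhenotypeVector", sampleIds = y@sampleIds[yi],
            values = y@values[yi], traitName = y@traitName,
            nDropped = y@nDropped)
  list(G = G2, y = y2)
}

#' Split n individuals into outer train and test sets
#'
#' Uniformly random partition with `round(n * testFraction)` test
#' individuals; deterministic under `seed`.
#'
#' @param n number of individuals.
#' @param testFraction proportion in (0, 1) assigned to the test set
#'   (default 0.2).
#' @param seed integer seed.
#' @return A [DataSplit-class].
#' @export
outerSplit <- function(n, testFraction = 0.2, seed = 1L) {
  n <- as.integer(n)
  .assertScalarNumber(testFraction, "testFraction")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)", call. = FALSE)
  nTest <- as.integer(round(n * testFraction))
  if (n < 2L || nTest < 1L || nTest >= n)
    stop(sprintf("cannot split n = %d with testFraction = %g", n, testFraction),
         call. = FALSE)
  te <- sort(.withSeed(seed, sample.int(n, nTest)))
  new("DataSplit", trainIdx = setdiff(seq_len(n), te), testIdx = te, n = n)
}

#' Write observed/predicted pairs as TSV
#'
#' @param sampleIds identifiers.
#' @param observed,predicted numeric vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(sampleIds, observed, predicted, path) {
  data.table::fwrite(
    data.table::data.table(sample_id = sampleIds, observed = observed,
                           predicted = predicted),
    path, sep = "\t")
  invisible(path)
}
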