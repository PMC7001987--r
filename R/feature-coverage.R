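# Coverage featurization: feature sets from BED, coverage tracks from
# bigWig/bedGraph, and per-dataset TPM profiles over a fixed feature set.

FEATURE_CLASSES <- c("promoter", "gene_body", "transcript", "enhancer")

abort_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "covnet_validation_error")
}
abort_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "covnet_parse_error")
}
abort_io <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "covnet_io_error")
}
abort_lookup <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "covnet_lookup_error")
}

#' Construct a feature set
#'
#' A feature set is an ordered table of genomic intervals (0-based, half-open
#' coordinates) of one feature class on one assembly. The row order is fixed
#' and defines the index of every downstream TPM vector.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`, `name`.
#' @param feature_class One of `"promoter"`, `"gene_body"`, `"transcript"`,
#'   `"enhancer"`.
#' @param assembly Genome assembly label (e.g. `"hg19"`).
#' @return A `feature_set` tibble with `assembly` and `feature_class`
#'   attributes.
#' @export
feature_set <- function(intervals, feature_class, assembly) {
  feature_class <- arg_match0(feature_class, FEATURE_CLASSES)
  intervals <- as_tibble(intervals)
  required <- c("chrom", "start", "end", "name")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols) > 0) {
    abort_validation("feature set is missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  intervals <- intervals[required]
  if (any(intervals$start >= intervals$end)) {
    bad <- which(intervals$start >= intervals$end)[1]
    abort_validation("interval %d ('%s') has start >= end (%d >= %d)",
                     bad, intervals$name[bad],
                     intervals$start[bad], intervals$end[bad])
  }
  if (anyDuplicated(intervals$name)) {
    abort_validation("feature names are not unique (e.g. '%s')",
                     intervals$name[duplicated(intervals$name)][1])
  }
  structure(intervals,
            class = c("feature_set", class(intervals)),
            assembly = assembly,
            feature_class = feature_class)
}

#' Read a feature list from a BED file
#'
#' Accepts BED3 or BED4+; column 4 is used as the feature name when present,
#' otherwise names are synthesized as `chrom:start-end`. Coordinates are kept
#' 0-based half-open, and file order is preserved (it defines the profile
#' vector index).
#'
#' @param path Path to a BED file.
#' @inheritParams feature_set
#' @return A [feature_set()] tibble.
#' @export
read_feature_bed <- function(path, feature_class, assembly) {
  if (!file.exists(path)) abort_io("cannot read BED file '%s'", path)
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) abort_parse("no intervals in BED file '%s'", path)
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) < 3) {
      abort_parse("line %d of '%s': expected >= 3 BED columns, found %d",
                  i, path, length(fields))
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end)) {
      abort_parse("line %d of '%s': non-numeric coordinates", i, path)
    }
    if (start >= end) {
      abort_validation("line %d of '%s': start >= end (%d >= %d)",
                       i, path, start, end)
    }
    name <- if (length(fields) >= 4) fields[4] else
      sprintf("%s:%d-%d", fields[1], start, end)
    tibble(chrom = fields[1], start = start, end = end, name = name)
  })
  feature_set(bind_rows(parsed), feature_class, assembly)
}

#' Write a feature set as BED4
#'
#' @param features A [feature_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_bed <- function(features, path) {
  readr::write_tsv(as_tibble(features)[c("chrom", "start", "end", "name")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a coverage track
#'
#' Reads a bigWig (via rtracklayer) or a bedGraph text file into a tibble of
#' non-overlapping intervals with coverage values. Coordinates are reported
#' 0-based half-open. Tracks are unstranded; negative values are rejected.
#'
#' @param path Path to a `.bw`/`.bigWig` or `.bedGraph`/`.bg` file.
#' @param format Override format detection: `"bigWig"` or `"bedGraph"`.
#' @return A `coverage_track` tibble with columns `chrom`, `start`, `end`,
#'   `value`.
#' @export
read_track <- function(path, format = NULL) {
  if (!file.exists(path)) abort_io("cannot read coverage track '%s'", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bw", "bigwig")) "bigWig" else "bedGraph"
  }
  gr <- tryCatch(
    if (format == "bigWig") rtracklayer::import(path, format = "BigWig")
    else rtracklayer::import(path, format = "bedGraph"),
    error = function(e) abort_io("failed to read track '%s': %s",
                                 path, conditionMessage(e))
  )
  track <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
  validate_track(track)
}

validate_track <- function(track) {
  track <- as_tibble(track)[c("chrom", "start", "end", "value")]
  if (any(is.na(track$value))) abort_validation("track has missing values")
  if (any(track$value < 0)) {
    abort_validation("track has negative coverage values (min %g)",
                     min(track$value))
  }
  structure(track, class = c("coverage_track", class(track)))
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track` tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(as_tibble(track)[c("chrom", "start", "end", "value")],
                   path, col_names = FALSE)
  invisible(path)
}

track_as_coverage <- function(track) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  GenomicRanges::coverage(gr, weight = track$value)
}

#' Sum coverage over each feature
#'
#' For each interval the per-base track values over `[start, end)` are summed.
#' Features on chromosomes absent from the track, and bases beyond the track's
#' extent, contribute zero.
#'
#' @param track A `coverage_track` tibble or path readable by [read_track()].
#' @param features A [feature_set()].
#' @return A tibble with columns `name`, `length` (bp) and `count`.
#' @export
extract_counts <- function(track, features) {
  if (is.character(track)) track <- read_track(track)
  track <- validate_track(track)
  cov <- track_as_coverage(track)
  counts <- numeric(nrow(features))
  for (chr in unique(features$chrom)) {
    idx <- which(features$chrom == chr)
    if (!chr %in% names(cov)) next
    rle <- cov[[chr]]
    s <- pmax(features$start[idx] + 1L, 1L)
    e <- pmin(features$end[idx], length(rle))
    ok <- s <= e
    if (any(ok)) {
      counts[idx[ok]] <- as.numeric(
        sum(IRanges::Views(rle, start = s[ok], end = e[ok]))
      )
    }
  }
  tibble(name = features$name,
         length = features$end - features$start,
         count = counts)
}

#' Convert per-feature coverage sums to TPM
#'
#' Standard length-normalized TPM: rates `count/length` rescaled to sum to
#' 10^6. An all-zero count vector maps to an all-zero TPM vector (degenerate
#' datasets are kept but flagged downstream).
#'
#' @param counts Non-negative per-feature coverage sums.
#' @param lengths Positive per-feature lengths in bp.
#' @return Numeric TPM vector of the same length.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    abort_validation("counts and lengths differ in length (%d vs %d)",
                     length(counts), length(lengths))
  }
  if (any(lengths <= 0)) abort_validation("feature lengths must be positive")
  if (any(counts < 0)) abort_validation("counts must be non-negative")
  rates <- counts / lengths
  total <- sum(rates)
  if (total == 0) return(rep(0, length(counts)))
  1e6 * rates / total
}

#' Construct a dataset record
#'
#' One row of dataset metadata: identity, assembly, experiment type, annotated
#' cell type and (where the assay has one) target, plus ownership and
#' visibility. An experiment groups one or more datasets (replicates or
#' re-alignments of the same biological sample); `target = NA` is legal for
#' assays such as RNA-seq where the field is not applicable.
#'
#' @param dataset_id,experiment_id Identifiers; `experiment_id` defaults to
#'   `dataset_id`.
#' @param assembly,experiment_type Assembly label and assay (e.g. "RNA-seq").
#' @param cell_type Free-text cell/tissue term (matched to an ontology later).
#' @param target Free-text target term or `NA`.
#' @param owner Owning user id.
#' @param public Visibility flag; private datasets stay visible to their owner
#'   and to the recommendation engine run on the owner's behalf.
#' @return A one-row tibble.
#' @export
dataset_record <- function(dataset_id, assembly, experiment_type, cell_type,
                           target = NA_character_,
                           experiment_id = dataset_id,
                           owner = NA_character_, public = TRUE) {
  tibble(dataset_id = dataset_id, experiment_id = experiment_id,
         assembly = assembly, experiment_type = experiment_type,
         cell_type = cell_type, target = as.character(target),
         owner = owner, public = public)
}

#' Build a TPM profile for one dataset
#'
#' Sums coverage over the feature set, converts to TPM and attaches the
#' dataset's identity. Raw coverage is not retained. A zero-signal track is
#' accepted but the profile is flagged degenerate (and excluded from
#' classifier training).
#'
#' @param record A one-row tibble from [dataset_record()].
#' @param track A `coverage_track` or path.
#' @param features A [feature_set()] on the record's assembly.
#' @return A `dataset_profile` tibble (`name`, `length`, `count`, `tpm`) with
#'   identity attributes.
#' @export
build_profile <- function(record, track, features) {
  if (!identical(record$assembly, attr(features, "assembly"))) {
    abort_validation("record assembly '%s' does not match feature set '%s'",
                     record$assembly, attr(features, "assembly"))
  }
  counts <- extract_counts(track, features)
  counts$tpm <- compute_tpm(counts$count, counts$length)
  structure(counts,
            class = c("dataset_profile", class(counts)),
            dataset_id = record$dataset_id,
            assembly = record$assembly,
            experiment_type = record$experiment_type,
            feature_class = attr(features, "feature_class"),
            degenerate = sum(counts$count) == 0)
}

#' Assemble profiles into a feature-by-dataset matrix
#'
#' @param profiles A list of `dataset_profile` tibbles over the same feature
#'   set.
#' @return A numeric matrix, rows = features, columns = dataset ids.
#' @export
profiles_to_matrix <- function(profiles) {
  ids <- map_chr(profiles, ~ attr(.x, "dataset_id"))
  if (anyDuplicated(ids)) abort_validation("duplicate dataset ids in profiles")
  nm <- profiles[[1]]$name
  mats <- map(profiles, function(p) {
    if (!identical(p$name, nm)) {
      abort_validation("profiles are not aligned to the same feature set")
    }
    p$tpm
  })
  mat <- do.call(cbind, mats)
  dimnames(mat) <- list(nm, ids)
  mat
}

#' Write / read a profile matrix with its metadata sidecar
#'
#' The matrix is written as TSV (rows = features, columns = datasets, first
#' column `feature`) with the dataset records as a JSON sidecar, mirroring the
#' persisted form used for downstream comparison.
#'
#' @param mat Feature-by-dataset matrix.
#' @param records Tibble of [dataset_record()] rows covering the columns.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profile_matrix <- function(mat, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- as_tibble(mat, rownames = "feature")
  readr::write_tsv(tb, file.path(dir, "profiles.tsv"))
  jsonlite::write_json(records, file.path(dir, "records.json"),
                       dataframe = "rows", na = "null", auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(dir) {
  tb <- readr::read_tsv(file.path(dir, "profiles.tsv"),
                        show_col_types = FALSE)
  mat <- as.matrix(tb[-1])
  rownames(mat) <- tb$feature
  records <- as_tibble(jsonlite::fromJSON(file.path(dir, "records.json")))
  list(matrix = mat, records = records)
}
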