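# All internal coordinates are 0-based half-open. 1-based inclusive
# conventions exist only at the format boundaries (SAM POS, RepeatMasker
# begin/end) and are converted on read.

REPEAT_ROLES <- c("five_prime_ltr", "internal", "three_prime_ltr",
                  "solo", "unassigned")

#' Construct a repeat annotation
#'
#' A repeat annotation is the hierarchical (class -> family -> subfamily ->
#' instance) interval set that every counting stage consumes. Intervals are
#' stored 0-based half-open and sorted by (contig, start, end); input order
#' is preserved among exact ties.
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`,
#'   `strand` ("+"/"-"), `subfamily`, `family`, `repclass` (e.g. "LTR",
#'   "LINE", "SINE", "DNA"), optional `role` (one of `five_prime_ltr`,
#'   `internal`, `three_prime_ltr`, `solo`, `unassigned`) and optional
#'   `instance_id` (unique; auto-assigned as "<subfamily>.<ordinal>" when
#'   absent).
#' @param background_classes character vector of repeat classes treated as
#'   transcriptionally inactive background (default `"DNA"`, the murine DNA
#'   transposons).
#' @return an object of class `RepeatAnnotation`: a list with elements
#'   `intervals` (the validated data.frame) and `background_classes`.
#' @export
repeat_annotation <- function(intervals, background_classes = "DNA") {
  req <- c("contig", "start", "end", "strand", "subfamily", "family",
           "repclass")
  missing_cols <- setdiff(req, names(intervals))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(intervals) > 0L) {
    if (!is.numeric(intervals$start) || !is.numeric(intervals$end)) {
      stop("start/end must be numeric")
    }
    if (any(intervals$start < 0)) stop("negative start coordinate")
    if (any(intervals$end <= intervals$start)) {
      bad <- which(intervals$end <= intervals$start)[1L]
      stop("interval ", bad, ": end must exceed start")
    }
    if (any(!intervals$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  if (is.null(intervals$role)) intervals$role <- rep("unassigned", nrow(intervals))
  if (nrow(intervals) > 0L && any(!intervals$role %in% REPEAT_ROLES)) {
    stop("unknown role(s): ",
         paste(setdiff(unique(intervals$role), REPEAT_ROLES), collapse = ", "))
  }
  if (is.null(intervals$instance_id)) {
    ord <- stats::ave(seq_len(nrow(intervals)), intervals$subfamily,
                      FUN = seq_along)
    intervals$instance_id <- if (nrow(intervals) > 0L) {
      paste0(intervals$subfamily, ".", ord)
    } else character(0)
  }
  if (anyDuplicated(intervals$instance_id)) {
    stop("instance_id values are not unique")
  }
  o <- order(intervals$contig, intervals$start, intervals$end)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals,
                 background_classes = background_classes),
            class = "RepeatAnnotation")
}

#' @export
print.RepeatAnnotation <- function(x, ...) {
  iv <- x$intervals
  cat("RepeatAnnotation:", nrow(iv), "intervals,",
      length(unique(iv$subfamily)), "subfamilies,",
      length(unique(iv$repclass)), "classes",
      "(background:", paste(x$background_classes, collapse = ","), ")\n")
  invisible(x)
}

#' Total length (bp) of each repeat unit
#'
#' A unit is a subfamily (default), family or class; its length is the sum of
#' its interval lengths and must be positive for any unit that is quantified.
#'
#' @param annotation a `RepeatAnnotation`
#' @param level `"subfamily"`, `"family"` or `"repclass"`
#' @return named numeric vector of unit lengths in bp
#' @export
unit_lengths <- function(annotation, level = "subfamily") {
  iv <- annotation$intervals
  if (!level %in% c("subfamily", "family", "repclass")) {
    stop("unknown level: ", level)
  }
  if (nrow(iv) == 0L) return(stats::setNames(numeric(0), character(0)))
  lens <- tapply(iv$end - iv$start, iv[[level]], sum)
  out <- as.numeric(lens)
  names(out) <- names(lens)
  out[order(names(out))]
}

# subfamily -> (family, class) lookup; errors on inconsistent hierarchy
unit_class_map <- function(annotation, level = "subfamily") {
  iv <- annotation$intervals
  m <- unique(iv[, c(level, "repclass")])
  if (anyDuplicated(m[[level]])) {
    stop("unit maps to more than one class at level ", level)
  }
  stats::setNames(m$repclass, m[[level]])
}

annotation_granges <- function(annotation) {
  iv <- annotation$intervals
  GenomicRanges::GRanges(
    seqnames = iv$contig,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = iv$strand
  )
}

#' Read a repeat annotation from BED6
#'
#' The BED name field encodes the RepeatMasker-style hierarchy as
#' `subfamily|family|class|role` (role optional, defaults to `unassigned`),
#' so the annotation travels in a standard format.
#'
#' @param path BED file, >= 6 tab-separated fields per line
#' @param background_classes passed to [repeat_annotation()]
#' @return a `RepeatAnnotation`
#' @export
read_repeat_bed <- function(path, background_classes = "DNA") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(repeat_annotation(data.frame(
      contig = character(0), start = numeric(0), end = numeric(0),
      strand = character(0), subfamily = character(0), family = character(0),
      repclass = character(0), role = character(0),
      stringsAsFactors = FALSE), background_classes))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 6L)) {
    stop("malformed BED line ", which(n < 6L)[1L], ": fewer than 6 fields")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         ": non-numeric coordinate")
  }
  name_parts <- strsplit(get(4), "|", fixed = TRUE)
  np <- lengths(name_parts)
  if (any(np < 3L)) {
    stop("malformed BED line ", which(np < 3L)[1L],
         ": name must be 'subfamily|family|class[|role]'")
  }
  part <- function(i, default = NA_character_) {
    vapply(name_parts, function(p) if (length(p) >= i) p[[i]] else default,
           character(1))
  }
  repeat_annotation(data.frame(
    contig = get(1), start = start, end = end, strand = get(6),
    subfamily = part(1), family = part(2), repclass = part(3),
    role = ifelse(is.na(part(4, NA_character_)), "unassigned", part(4)),
    stringsAsFactors = FALSE), background_classes)
}

#' Write a repeat annotation as BED6 (inverse of [read_repeat_bed()])
#' @param annotation a `RepeatAnnotation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_repeat_bed <- function(annotation, path) {
  iv <- annotation$intervals
  lines <- if (nrow(iv) == 0L) character(0) else {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", iv$contig, as.integer(iv$start),
            as.integer(iv$end),
            paste(iv$subfamily, iv$family, iv$repclass, iv$role, sep = "|"),
            iv$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read imprinting control region (ICR) intervals from BED
#'
#' The BED name field is either the ICR name or `name|methylated_allele`
#' with allele in `maternal`/`paternal`/`unknown`.
#'
#' @param path BED file with >= 4 fields
#' @return data.frame with `contig`, `start`, `end`, `name`,
#'   `methylated_allele`
#' @export
read_icr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      methylated_allele = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("malformed ICR BED line ", which(lengths(fields) < 4L)[1L])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  parts <- strsplit(get(4), "|", fixed = TRUE)
  name <- vapply(parts, `[[`, character(1), 1L)
  allele <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "unknown",
                   character(1))
  out <- data.frame(contig = get(1), start = as.numeric(get(2)),
                    end = as.numeric(get(3)), name = name,
                    methylated_allele = allele, stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("ICR interval with end <= start")
  out
}

#' Write ICR intervals as BED4 (inverse of [read_icr_bed()])
#' @param icrs data.frame as returned by [read_icr_bed()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_icr_bed <- function(icrs, path) {
  lines <- if (nrow(icrs) == 0L) character(0) else {
    sprintf("%s\t%d\t%d\t%s", icrs$contig, as.integer(icrs$start),
            as.integer(icrs$end),
            paste(icrs$name, icrs$methylated_allele, sep = "|"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a RepeatMasker .out-style table
#'
#' Whitespace-delimited RepeatMasker rows (score, divergence, deletion,
#' insertion, query, begin, end, left, strand, repeat name, class/family,
#' ...). The 1-based inclusive begin/end are converted to 0-based half-open;
#' "class/family" is split on "/" (a bare class such as "DNA" yields
#' family = class); a "C" strand becomes "-"; roles are `unassigned`.
#' Header/blank lines (not starting with a numeric score) are skipped.
#'
#' @param path RepeatMasker table
#' @param background_classes passed to [repeat_annotation()]
#' @return a `RepeatAnnotation`
#' @export
read_repeatmasker_table <- function(path, background_classes = "DNA") {
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- grepl("^[0-9]", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(repeat_annotation(data.frame(
      contig = character(0), start = numeric(0), end = numeric(0),
      strand = character(0), subfamily = character(0), family = character(0),
      repclass = character(0), stringsAsFactors = FALSE), background_classes))
  }
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) < 11L)) {
    stop("RepeatMasker row ", which(lengths(fields) < 11L)[1L],
         ": missing class/family column")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  begin <- as.numeric(get(6))
  end <- as.numeric(get(7))
  strand <- ifelse(get(9) %in% c("C", "-"), "-", "+")
  cf <- strsplit(get(11), "/", fixed = TRUE)
  repclass <- vapply(cf, `[[`, character(1), 1L)
  family <- vapply(cf, function(p) if (length(p) >= 2L) p[[2L]] else p[[1L]],
                   character(1))
  repeat_annotation(data.frame(
    contig = get(5), start = begin - 1, end = end, strand = strand,
    subfamily = get(10), family = family, repclass = repclass,
    stringsAsFactors = FALSE), background_classes)
}

#' Construct an aligned-fragment set
#'
#' Fragments are per-sample genomic intervals (0-based half-open) with
#' strand, a multimapper flag and a duplicate flag, sorted by
#' (contig, start, end).
#'
#' @param df data.frame with `contig`, `start`, `end`, `strand` and optional
#'   logical `multimapper`, `duplicate`
#' @param n_skipped number of input records dropped as unmapped (recorded as
#'   an attribute)
#' @return data.frame of class `AlignedFragmentSet`
#' @export
fragment_set <- function(df, n_skipped = 0L) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("contig", "start", "end", "strand")
  if (length(setdiff(req, names(df))) > 0L) {
    stop("fragment set needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(df$start < 0)) stop("negative fragment coordinate")
    if (any(df$end <= df$start)) stop("fragment with end <= start")
  }
  if (is.null(df$multimapper)) df$multimapper <- rep(FALSE, nrow(df))
  if (is.null(df$duplicate)) df$duplicate <- rep(FALSE, nrow(df))
  df <- df[, c(req, "multimapper", "duplicate")]
  o <- order(df$contig, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_skipped") <- as.integer(n_skipped)
  class(df) <- c("AlignedFragmentSet", "data.frame")
  df
}

#' Read aligned fragments from SAM or BED
#'
#' SAM dialect: plain-text, header optional; unmapped records (FLAG bit 4)
#' are skipped and the skipped count is recorded in the `n_skipped`
#' attribute and logged to stderr; POS is 1-based and the end coordinate is
#' POS - 1 + CIGAR reference length (M/D/N/=/X). The multimapper flag is set
#' for records with mapping quality 0 (the convention of aligners that
#' report a single random alignment per multimapping read; override with
#' `multimapper_mapq`). BED dialect: chrom/start/end(/name/score/strand),
#' strand defaulting to "+" when absent.
#'
#' @param path input file
#' @param dialect `"sam"` or `"bed"`
#' @param multimapper_mapq SAM records with MAPQ <= this value are flagged
#'   multimapper (default 0)
#' @return an `AlignedFragmentSet`
#' @export
read_fragments <- function(path, dialect = c("bed", "sam"),
                           multimapper_mapq = 0L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (dialect == "bed") {
    if (length(lines) == 0L) return(fragment_set(empty_fragments()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L)) {
      stop("malformed BED line ", which(lengths(fields) < 3L)[1L])
    }
    get <- function(i, default) {
      vapply(fields, function(p) if (length(p) >= i) p[[i]] else default,
             character(1))
    }
    df <- data.frame(
      contig = get(1, NA_character_),
      start = as.numeric(get(2, NA_character_)),
      end = as.numeric(get(3, NA_character_)),
      strand = ifelse(get(6, "+") %in% c("+", "-"), get(6, "+"), "+"),
      stringsAsFactors = FALSE)
    if (any(df$start < 0)) stop("negative coordinate in BED fragment file")
    return(fragment_set(df))
  }
  # SAM
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(fragment_set(empty_fragments()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("malformed SAM record ", which(lengths(fields) < 11L)[1L])
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  n_skipped <- sum(unmapped)
  if (n_skipped > 0L) {
    message("read_fragments: skipped ", n_skipped, " unmapped record(s)")
  }
  fields <- fields[!unmapped]
  flag <- flag[!unmapped]
  if (length(fields) == 0L) return(fragment_set(empty_fragments(), n_skipped))
  pos <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  mapq <- as.integer(vapply(fields, `[[`, character(1), 5L))
  cigar <- vapply(fields, `[[`, character(1), 6L)
  reflen <- cigar_reference_length(cigar)
  df <- data.frame(
    contig = vapply(fields, `[[`, character(1), 3L),
    start = pos - 1,
    end = pos - 1 + reflen,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    multimapper = mapq <= multimapper_mapq,
    stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("negative coordinate in SAM record")
  fragment_set(df, n_skipped)
}

empty_fragments <- function() {
  data.frame(contig = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

# reference-consuming CIGAR length: sum of M, D, N, =, X operations
cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) stop("malformed CIGAR: ", cg)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.numeric(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write fragments as BED6
#' @param fragments an `AlignedFragmentSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fragments_bed <- function(fragments, path) {
  lines <- if (nrow(fragments) == 0L) character(0) else {
    sprintf("%s\t%d\t%d\t.\t0\t%s", fragments$contig,
            as.integer(fragments$start), as.integer(fragments$end),
            fragments$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-bp coverage as bedGraph
#'
#' Values are run-length merged into 0-based half-open intervals; zero runs
#' are omitted, so a read-back padded with zeros reproduces the input
#' exactly.
#'
#' @param coverage named list: one numeric per-bp vector per contig
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(coverage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (contig in names(coverage)) {
    v <- coverage[[contig]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("coverage for ", contig, " contains NaN/negative values")
    }
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.15g", contig,
                         as.integer(starts[keep]), as.integer(ends[keep]),
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Read a bedGraph back into per-bp coverage vectors
#' @param path bedGraph file
#' @param contig_lengths optional named vector; vectors are zero-padded to
#'   these lengths (default: up to the last covered base per contig)
#' @return named list of numeric vectors
#' @export
read_bedgraph <- function(path, contig_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  if (length(lines) > 0L) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    contig <- vapply(fields, `[[`, character(1), 1L)
    start <- as.integer(vapply(fields, `[[`, character(1), 2L))
    end <- as.integer(vapply(fields, `[[`, character(1), 3L))
    value <- as.numeric(vapply(fields, `[[`, character(1), 4L))
    for (ct in unique(contig)) {
      i <- contig == ct
      len <- if (!is.null(contig_lengths) && ct %in% names(contig_lengths)) {
        contig_lengths[[ct]]
      } else max(end[i])
      v <- numeric(len)
      for (j in which(i)) v[(start[j] + 1L):end[j]] <- value[j]
      out[[ct]] <- v
    }
  }
  if (!is.null(contig_lengths)) {
    for (ct in setdiff(names(contig_lengths), names(out))) {
      out[[ct]] <- numeric(contig_lengths[[ct]])
    }
    out <- out[names(contig_lengths)]
  }
  out
}

#' Construct and validate a sample manifest
#'
#' The manifest maps sample files to experimental roles. Every ChIP group
#' must have a matched control group (input or IgG) under the same
#' target/condition key, mirroring how enrichment is defined (mean of ChIP
#' replicates over mean of control replicates).
#'
#' @param df data.frame with columns `sample_id`, `path`, `assay`
#'   (chip/input/igg/rna), `target` (e.g. "O-GlcNAc", "TRIM28"; may be ""),
#'   `condition`, `replicate`
#' @return data.frame of class `SampleManifest`
#' @export
sample_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "path", "assay", "target", "condition", "replicate")
  if (length(setdiff(req, names(df))) > 0L) {
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in manifest")
  if (any(!df$assay %in% c("chip", "input", "igg", "rna"))) {
    stop("unknown assay; must be chip/input/igg/rna")
  }
  if (any(df$replicate < 1)) stop("replicate must be a positive integer")
  chip <- df[df$assay == "chip", , drop = FALSE]
  for (key in unique(paste(chip$target, chip$condition, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    tgt <- parts[1]; cond <- if (length(parts) > 1) parts[2] else ""
    ctrl <- df$assay %in% c("input", "igg") & df$condition == cond &
      (df$target == tgt | df$target == "")
    if (!any(ctrl)) {
      stop("chip group (target=", tgt, ", condition=", cond,
           ") has no matched input/igg control")
    }
  }
  class(df) <- c("SampleManifest", "data.frame")
  df
}

#' Read a sample manifest TSV
#' @param path TSV with a header row naming the manifest columns
#' @return a `SampleManifest`
#' @export
read_sample_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  df$replicate <- as.integer(df$replicate)
  sample_manifest(df)
}

# match manifest rows against a named key, e.g.
# list(assay = "chip", target = "O-GlcNAc", condition = "WT");
# "" in the manifest target matches any requested target for control assays
manifest_select <- function(manifest, key) {
  keep <- rep(TRUE, nrow(manifest))
  for (field in names(key)) {
    if (!field %in% names(manifest)) stop("unknown manifest field: ", field)
    v <- manifest[[field]]
    if (field == "target") {
      keep <- keep & (v == key[[field]] | v == "")
    } else {
      keep <- keep & v == key[[field]]
    }
  }
  manifest$sample_id[keep]
}
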