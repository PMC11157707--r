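#' Construct a FragmentSample
#'
#' Low-level constructor validating the fragment/mismatch invariants.
#'
#' @param sampleId Sample identifier.
#' @param fragments `data.frame` with columns `chrom`, `start`, `end`, `gc`,
#'   `mapq`, `n_mismatch` (and optionally `length`, recomputed if absent).
#' @param mismatches `data.frame` with columns `frag`, `pos`, `ref_tri`,
#'   `alt`, `baseq`; default empty.
#' @param label `"cancer"`, `"non_cancer"` or `"unknown"`.
#' @param metadata Optional list of sample annotations.
#' @return A [FragmentSample-class].
#' @export
FragmentSample <- function(sampleId, fragments, mismatches = emptyMismatches(),
                           label = "unknown", metadata = list()) {
  fragments <- as.data.frame(fragments)
  if (is.null(fragments$length))
    fragments$length <- fragments$end - fragments$start
  fragments <- fragments[, .fragmentCols, drop = FALSE]
  rownames(fragments) <- NULL
  mismatches <- as.data.frame(mismatches)[, .mismatchCols, drop = FALSE]
  rownames(mismatches) <- NULL
  methods::new("FragmentSample", sampleId = as.character(sampleId),
               label = label, fragments = fragments,
               mismatches = mismatches, metadata = metadata)
}

#' Empty mismatch table
#' @return Zero-row `data.frame` with the mismatch columns.
#' @export
emptyMismatches <- function() {
  data.frame(frag = integer(), pos = integer(), ref_tri = character(),
             alt = character(), baseq = integer())
}

## serialize per-fragment mismatch lists as ";"-joined "pos,ref_tri,alt,baseq"
.packMismatches <- function(fragments, mismatches) {
  out <- rep(".", nrow(fragments))
  if (nrow(mismatches)) {
    tup <- sprintf("%d,%s,%s,%d", mismatches$pos, mismatches$ref_tri,
                   mismatches$alt, mismatches$baseq)
    packed <- vapply(split(tup, mismatches$frag), paste,
                     character(1), collapse = ";")
    out[as.integer(names(packed))] <- packed
  }
  out
}

.unpackMismatches <- function(strings) {
  has <- which(!is.na(strings) & strings != "." & nzchar(strings))
  if (!length(has)) return(emptyMismatches())
  tuples <- strsplit(strings[has], ";", fixed = TRUE)
  frag <- rep(has, lengths(tuples))
  parts <- strsplit(unlist(tuples), ",", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("malformed mismatch tuple at fragment row(s) ",
         paste(unique(frag[lengths(parts) != 4L])[1:1], collapse = ", "))
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(frag = frag, pos = as.integer(m[, 1]), ref_tri = m[, 2],
             alt = m[, 3], baseq = as.integer(m[, 4]))
}

#' Read a fragment table
#'
#' Canonical TSV dialect: header
#' `chrom start end gc mapq n_mismatch mismatches`, coordinates 0-based
#' half-open, `mismatches` either `.` or `;`-separated
#' `pos,ref_tri,alt,baseq` tuples. All [FragmentSample-class] invariants are
#' enforced on read; violations raise errors naming the offending row.
#'
#' @param path Path to the TSV file.
#' @param sampleId Sample identifier; defaults to the file name without
#'   extension.
#' @param label Sample label, default `"unknown"`.
#' @return A [FragmentSample-class].
#' @seealso [writeFragmentTable()]
#' @export
readFragmentTable <- function(path, sampleId = NULL, label = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  need <- c("chrom", "start", "end", "gc", "mapq", "n_mismatch", "mismatches")
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, need))
    stop("fragment table header must be: ", paste(need, collapse = "\t"))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = "mismatches"),
                           data.table = FALSE, showProgress = FALSE)
  for (col in c("start", "end", "mapq", "n_mismatch")) {
    v <- tab[[col]]
    if (nrow(tab) && (!is.numeric(v) || anyNA(v)))
      stop("malformed ", col, " at row ",
           which(!is.finite(suppressWarnings(as.numeric(v))) | is.na(v))[1])
    tab[[col]] <- as.integer(v)
  }
  if (nrow(tab) && (!is.numeric(tab$gc) || anyNA(tab$gc)))
    stop("malformed gc at row ", which(is.na(tab$gc))[1])
  tab$gc <- as.numeric(tab$gc)
  tab$chrom <- as.character(tab$chrom)
  mm <- .unpackMismatches(tab$mismatches)
  FragmentSample(sampleId,
                 fragments = tab[, c("chrom", "start", "end", "gc", "mapq",
                                     "n_mismatch")],
                 mismatches = mm, label = label)
}

#' Write a fragment table
#'
#' Inverse of [readFragmentTable()]; the round trip is lossless.
#'
#' @param sample A [FragmentSample-class].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeFragmentTable <- function(sample, path) {
  stopifnot(methods::is(sample, "FragmentSample"))
  fr <- sample@fragments
  out <- data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                    gc = fr$gc, mapq = fr$mapq, n_mismatch = fr$n_mismatch,
                    mismatches = .packMismatches(fr, sample@mismatches))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a SNP/CHIP position blacklist
#'
#' TSV with header `chrom pos ref alt`: positions whose substitution calls are
#' removed from spectra — germline SNPs or recurrent clonal-hematopoiesis
#' (CHIP) mutations.
#'
#' @param path Path to the TSV file.
#' @return `data.frame(chrom, pos, ref, alt)`.
#' @export
readBlacklist <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!identical(names(tab), need))
    stop("blacklist header must be: ", paste(need, collapse = "\t"))
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Write a position blacklist
#' @param blacklist `data.frame(chrom, pos, ref, alt)`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeBlacklist <- function(blacklist, path) {
  data.table::fwrite(blacklist[, c("chrom", "pos", "ref", "alt")], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a TF-site panel (BED)
#'
#' BED records `chrom center-1 center name`, one row per binding site; `name`
#' is the transcription factor.
#'
#' @param path Path to the BED file.
#' @return `data.frame(tf, chrom, center)`.
#' @export
readTFPanel <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE, showProgress = FALSE)
  if (ncol(tab) < 4L) stop("TF panel BED needs 4 columns: chrom start end name")
  data.frame(tf = tab[[4]], chrom = tab[[1]], center = as.integer(tab[[3]]))
}

#' Write a TF-site panel (BED)
#' @param panel `data.frame(tf, chrom, center)`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
writeTFPanel <- function(panel, path) {
  data.table::fwrite(data.frame(panel$chrom, panel$center - 1L, panel$center,
                                panel$tf),
                     path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
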