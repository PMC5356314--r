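#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## GRanges view of a peak track: 0-based half-open [start, end) becomes the
## 1-based closed range [start + 1, end], the same convention as
## pos_overlaps_interval().
track_granges <- function(track) {
  iv <- track$intervals
  GRanges(norm_chrom(iv$chrom), IRanges(iv$start + 1L, iv$end))
}

variant_granges <- function(variants) {
  GRanges(norm_chrom(variants$chrom), IRanges(variants$pos, variants$pos))
}

feature_colnames <- function(marks) {
  as.vector(t(outer(marks, c("Hit", "Intensity", "Centrality"),
                    function(m, f) paste(m, f, sep = "_"))))
}

check_tracks <- function(tracks) {
  if (!length(tracks)) return(invisible(NULL))
  marks <- vapply(tracks, function(t) t$mark, "")
  if (anyDuplicated(marks)) {
    stop("duplicate mark among tracks: ", marks[duplicated(marks)][1L])
  }
  cts <- unique(vapply(tracks, function(t) t$cell_type, ""))
  if (length(cts) > 1L) {
    stop("tracks must share one cell_type; got: ", paste(cts, collapse = ", "))
  }
  invisible(NULL)
}

#' Extract per-variant chromatin features for one cell type
#'
#' For each mark with a supplied track, three features per variant:
#' \describe{
#'   \item{Hit}{1 if the variant position falls inside a peak, else 0.}
#'   \item{Intensity}{signalValue of the overlapping peak (maximum if the
#'     variant falls in several), 0 without an overlap.}
#'   \item{Centrality}{distance in bp between the variant and the summit of
#'     the overlapping peak (nearest summit if several); without an overlap
#'     the fixed `sentinel` distance.}
#' }
#' Marks without a track yield an NA feature triple (flagged in the
#' `missing_marks` attribute) unless `zero_fill = TRUE`, in which case they
#' are encoded like a non-overlap.
#'
#' With all 12 marks supplied each row has 12 x 3 = 36 columns, ordered by
#' mark name (alphabetical) then Hit, Intensity, Centrality.
#'
#' @param variants variant data frame (see [read_variants()]).
#' @param tracks list of `peak_track` objects sharing one cell type, at most
#'   one per mark.
#' @param marks marks defining the column layout. Defaults to the marks of
#'   the supplied tracks (sorted), so an 11-track run yields 33 columns; an
#'   empty track list defaults to the full panel [REGPOT_MARKS]. Request
#'   marks beyond the supplied tracks to obtain flagged missing triples.
#' @param sentinel Centrality value used when no peak overlaps (default
#'   10000 bp).
#' @param zero_fill encode missing marks as non-overlaps instead of NA.
#' @param log1p_intensity apply `log1p` to Intensity (default off; peak
#'   signal is used in its native units).
#' @return numeric matrix, one row per variant (rownames = variant ids), with
#'   attributes `cell_type` and `missing_marks`.
#' @export
feature_matrix <- function(variants, tracks, marks = NULL, sentinel = 10000,
                           zero_fill = FALSE, log1p_intensity = FALSE) {
  if (!is.data.frame(variants) || nrow(variants) == 0L) {
    stop("need a non-empty variant data frame")
  }
  check_tracks(tracks)
  if (is.null(marks)) {
    marks <- if (length(tracks)) {
      vapply(tracks, function(t) t$mark, "")
    } else {
      REGPOT_MARKS
    }
  }
  marks <- sort(match.arg(marks, REGPOT_MARKS, several.ok = TRUE),
                method = "radix")
  n <- nrow(variants)
  out <- matrix(NA_real_, nrow = n, ncol = 3L * length(marks),
                dimnames = list(variants$id, feature_colnames(marks)))
  have <- if (length(tracks)) vapply(tracks, function(t) t$mark, "") else character(0)
  vgr <- variant_granges(variants)
  for (tr in tracks) {
    mk <- tr$mark
    if (!mk %in% marks) next
    hit <- numeric(n); inten <- numeric(n); centr <- rep(sentinel, n)
    if (nrow(tr$intervals)) {
      ov <- findOverlaps(vgr, track_granges(tr))
      qi <- queryHits(ov); si <- subjectHits(ov)
      if (length(qi)) {
        iv <- tr$intervals
        summit <- peak_summit_pos(iv$start, iv$summit_offset)
        d <- abs(variants$pos[qi] - summit[si])
        sig <- iv$signal[si]
        for (grp in split(seq_along(qi), qi)) {
          i <- qi[grp[1L]]
          hit[i] <- 1
          inten[i] <- max(sig[grp])
          centr[i] <- min(d[grp])
        }
      }
    }
    if (log1p_intensity) inten <- log1p(inten)
    out[, paste0(mk, "_Hit")] <- hit
    out[, paste0(mk, "_Intensity")] <- inten
    out[, paste0(mk, "_Centrality")] <- centr
  }
  missing_marks <- setdiff(marks, have)
  if (zero_fill && length(missing_marks)) {
    for (mk in missing_marks) {
      out[, paste0(mk, "_Hit")] <- 0
      out[, paste0(mk, "_Intensity")] <- 0
      out[, paste0(mk, "_Centrality")] <- sentinel
    }
  }
  ct <- if (length(tracks)) tracks[[1L]]$cell_type else NA_character_
  structure(out, cell_type = ct,
            missing_marks = if (zero_fill) character(0) else missing_marks)
}

#' Extract the chromatin feature vector of a single variant
#'
#' Convenience wrapper around [feature_matrix()] for one variant.
#'
#' @param variant one-row variant data frame.
#' @inheritParams feature_matrix
#' @return named numeric vector of features (36 entries with all 12 marks).
#' @export
extract_features <- function(variant, tracks, marks = NULL, sentinel = 10000,
                             zero_fill = FALSE, log1p_intensity = FALSE) {
  stopifnot(is.data.frame(variant), nrow(variant) == 1L)
  m <- feature_matrix(variant, tracks, marks = marks, sentinel = sentinel,
                      zero_fill = zero_fill,
                      log1p_intensity = log1p_intensity)
  setNames(as.numeric(m[1L, ]), colnames(m))
}

#' Write a feature matrix as TSV
#'
#' Header: `variant_id` followed by `<MARK>_<Hit|Intensity|Centrality>`
#' columns.
#'
#' @param x feature matrix from [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  out <- data.frame(variant_id = rownames(x), x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path path to the TSV.
#' @return numeric matrix with variant ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[setdiff(names(df), "variant_id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$variant_id
  m
}
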