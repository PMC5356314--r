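#' @importFrom Biostrings letterFrequency subseq width
NULL

#' Distance from each variant to its nearest TSS
#'
#' @param variants variant data frame.
#' @param genes gene annotation (gene_id, chrom, tss, strand).
#' @return integer vector of distances in bp (Inf for variants on a
#'   chromosome with no annotated TSS).
#' @export
dist_to_nearest_tss <- function(variants, genes) {
  out <- rep(Inf, nrow(variants))
  vc <- norm_chrom(variants$chrom)
  gc_ <- norm_chrom(genes$chrom)
  for (chr in unique(vc)) {
    tss <- sort(genes$tss[gc_ == chr])
    if (!length(tss)) next
    idx <- which(vc == chr)
    pos <- variants$pos[idx]
    j <- findInterval(pos, tss)
    lo <- ifelse(j >= 1L, abs(pos - tss[pmax(j, 1L)]), Inf)
    hi <- ifelse(j < length(tss), abs(tss[pmin(j + 1L, length(tss))] - pos), Inf)
    out[idx] <- pmin(lo, hi)
  }
  out
}

#' GC content of the window around each variant
#'
#' Fraction of G/C bases in the `2 * flank + 1` bp window centred on the
#' variant (clipped at sequence ends).
#'
#' @param variants variant data frame.
#' @param seqs a named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences; names are matched after [norm_chrom()].
#' @param flank half-window in bp (default 50, i.e. a 101-bp window).
#' @return numeric vector of GC fractions in [0, 1].
#' @export
gc_window <- function(variants, seqs, flank = 50L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- norm_chrom(names(seqs))
  vc <- norm_chrom(variants$chrom)
  miss <- setdiff(unique(vc), names(seqs))
  if (length(miss)) {
    stop("no reference sequence for chromosome(s): ", paste(miss, collapse = ", "))
  }
  out <- numeric(nrow(variants))
  for (chr in unique(vc)) {
    s <- seqs[[chr]]
    idx <- which(vc == chr)
    lo <- pmax(variants$pos[idx] - flank, 1L)
    hi <- pmin(variants$pos[idx] + flank, length(s))
    v <- Biostrings::Views(s, start = lo, end = hi)
    cnt <- Biostrings::letterFrequency(v, letters = c("C", "G"))
    out[idx] <- rowSums(cnt) / (hi - lo + 1L)
  }
  out
}

## adjacency list of high-LD partners (r^2 > r2_max) from a pairwise table
high_ld_adjacency <- function(ld, r2_max) {
  adj <- new.env(parent = emptyenv())
  if (is.null(ld) || !nrow(ld)) return(adj)
  hi <- ld[ld$r^2 > r2_max, , drop = FALSE]
  add <- function(a, b) {
    cur <- if (exists(a, envir = adj, inherits = FALSE)) get(a, envir = adj) else character(0)
    assign(a, c(cur, b), envir = adj)
  }
  for (i in seq_len(nrow(hi))) {
    add(hi$snp_a[i], hi$snp_b[i])
    add(hi$snp_b[i], hi$snp_a[i])
  }
  adj
}

adj_get <- function(adj, id) {
  if (exists(id, envir = adj, inherits = FALSE)) get(id, envir = adj) else character(0)
}

new_matched_controls <- function(scheme, pairs, unmatched, seed) {
  structure(
    list(scheme = scheme, pairs = pairs, unmatched = unmatched, seed = seed),
    class = "matched_controls"
  )
}

#' @export
print.matched_controls <- function(x, ...) {
  cat(sprintf("<matched_controls> scheme=%s matched=%d unmatched=%d seed=%d\n",
              x$scheme, nrow(x$pairs), length(x$unmatched), x$seed))
  invisible(x)
}

empty_pairs <- function() {
  data.frame(case_id = character(0), control_id = character(0),
             af_case = numeric(0), af_control = numeric(0),
             dist_tss_case = numeric(0), dist_tss_control = numeric(0),
             stringsAsFactors = FALSE)
}

#' Random TSS-proximal, allele-frequency-matched control sampling
#'
#' For each case SNP, draws one control uniformly from the pool SNPs that
#' (i) deviate from the case allele frequency by less than `af_tol` and
#' (ii) lie within `tss_window` bp of some gene's TSS. Controls are drawn
#' without replacement across cases, in case order; a case with no eligible
#' candidate is reported unmatched and the run continues.
#'
#' @param cases,pool variant data frames; the pool must be disjoint from the
#'   cases.
#' @param genes gene annotation (gene_id, chrom, tss, strand).
#' @param seed integer seed; same seed, same control set.
#' @param af_tol allele-frequency deviation bound (strict; default 0.05).
#' @param tss_window maximal distance to the nearest TSS in bp (default
#'   10000).
#' @return a `matched_controls` object (scheme `"random_tss"`).
#' @export
sample_random_tss_controls <- function(cases, pool, genes, seed,
                                       af_tol = 0.05, tss_window = 10000L) {
  if (any(pool$id %in% cases$id)) stop("pool must be disjoint from cases")
  if (anyNA(pool$af)) stop("every pool SNP needs an allele frequency")
  set.seed(as.integer(seed))
  d_pool <- dist_to_nearest_tss(pool, genes)
  d_case <- dist_to_nearest_tss(cases, genes)
  near <- d_pool <= tss_window
  used <- logical(nrow(pool))
  rows <- vector("list", nrow(cases))
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    ok <- which(near & !used & abs(pool$af - cases$af[i]) < af_tol)
    if (!length(ok)) {
      unmatched <- c(unmatched, cases$id[i])
      next
    }
    pick <- if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1L)]
    used[pick] <- TRUE
    rows[[i]] <- data.frame(
      case_id = cases$id[i], control_id = pool$id[pick],
      af_case = cases$af[i], af_control = pool$af[pick],
      dist_tss_case = d_case[i], dist_tss_control = d_pool[pick],
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (any(!vapply(rows, is.null, TRUE))) {
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  } else {
    empty_pairs()
  }
  rownames(pairs) <- NULL
  if (length(unmatched)) {
    message(length(unmatched), " case(s) left unmatched under random_tss scheme")
  }
  new_matched_controls("random_tss", pairs, unmatched, as.integer(seed))
}

#' Strict matched-control sampling
#'
#' For each case SNP, draws one control uniformly from the pool SNPs that
#' pass all of:
#' \enumerate{
#'   \item LD exclusion: r^2 with the case, and with every high-LD partner
#'     of the case (r^2 > `r2_max`), is at most `r2_max` (pairs absent from
#'     the LD table count as r^2 = 0);
#'   \item allele-frequency deviation below `af_tol`;
#'   \item distance-to-nearest-TSS differing from the case by at most
#'     `tss_tol` bp;
#'   \item (when GC matching is on) GC content of the 101-bp window around
#'     the control within `gc_tol` of the case window.
#' }
#' Controls are drawn without replacement across cases; unmatched cases are
#' reported and the run continues.
#'
#' @inheritParams sample_random_tss_controls
#' @param ld pairwise LD table (snp_a, snp_b, r) or NULL for no LD
#'   information.
#' @param r2_max high-LD threshold on r^2 (default 0.8).
#' @param tss_tol TSS-distance deviation bound in bp (default 1000).
#' @param gc_tol GC-content deviation bound (default 0.05).
#' @param seqs chromosome sequences for GC computation (see [gc_window()]);
#'   alternatively supply `gc` directly.
#' @param gc named numeric vector of per-SNP window GC fractions covering
#'   cases and pool; overrides `seqs`.
#' @param match_gc enable the GC filter (default TRUE iff `gc` or `seqs`
#'   supplied). Requesting GC matching without sequence or GC input is an
#'   error.
#' @return a `matched_controls` object (scheme `"strict"`).
#' @export
sample_strict_controls <- function(cases, pool, genes, ld, seed,
                                   r2_max = 0.8, af_tol = 0.05,
                                   tss_tol = 1000L, gc_tol = 0.05,
                                   seqs = NULL, gc = NULL,
                                   match_gc = !is.null(gc) || !is.null(seqs)) {
  if (any(pool$id %in% cases$id)) stop("pool must be disjoint from cases")
  set.seed(as.integer(seed))
  if (match_gc) {
    if (is.null(gc)) {
      if (is.null(seqs)) {
        stop("GC matching requested but no reference sequence (`seqs`) or ",
             "precomputed `gc` supplied")
      }
      gc <- c(
        setNames(gc_window(cases, seqs), cases$id),
        setNames(gc_window(pool, seqs), pool$id)
      )
    }
    miss <- setdiff(c(cases$id, pool$id), names(gc))
    if (length(miss)) stop("no GC value for SNP(s): ", paste(head(miss, 3), collapse = ", "))
  }
  adj <- high_ld_adjacency(ld, r2_max)
  d_pool <- dist_to_nearest_tss(pool, genes)
  d_case <- dist_to_nearest_tss(cases, genes)
  used <- logical(nrow(pool))
  rows <- vector("list", nrow(cases))
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    cid <- cases$id[i]
    proxies <- adj_get(adj, cid)
    excl <- unique(c(
      proxies,
      unlist(lapply(proxies, adj_get, adj = adj), use.names = FALSE)
    ))
    ok <- !used &
      !(pool$id %in% excl) &
      abs(pool$af - cases$af[i]) < af_tol &
      abs(d_pool - d_case[i]) <= tss_tol
    if (match_gc) {
      ok <- ok & abs(gc[pool$id] - gc[cid]) <= gc_tol
    }
    ok <- which(ok)
    if (!length(ok)) {
      unmatched <- c(unmatched, cid)
      next
    }
    pick <- if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1L)]
    used[pick] <- TRUE
    rows[[i]] <- data.frame(
      case_id = cid, control_id = pool$id[pick],
      af_case = cases$af[i], af_control = pool$af[pick],
      dist_tss_case = d_case[i], dist_tss_control = d_pool[pick],
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (any(!vapply(rows, is.null, TRUE))) {
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  } else {
    empty_pairs()
  }
  rownames(pairs) <- NULL
  if (length(unmatched)) {
    message(length(unmatched), " case(s) left unmatched under strict scheme")
  }
  new_matched_controls("strict", pairs, unmatched, as.integer(seed))
}

#' Independently re-check a matched control set against its constraints
#'
#' Re-derives every filter from the raw inputs (not from the sampler's
#' internals) and reports which pairs satisfy all scheme constraints.
#'
#' @param set a `matched_controls` object.
#' @param cases,pool,genes,ld,gc,seqs the inputs given to the sampler.
#' @param af_tol,tss_window,r2_max,tss_tol,gc_tol the sampler's thresholds.
#' @return logical vector, one entry per pair, TRUE when all constraints
#'   hold.
#' @export
verify_controls <- function(set, cases, pool, genes, ld = NULL,
                            gc = NULL, seqs = NULL,
                            af_tol = 0.05, tss_window = 10000L,
                            r2_max = 0.8, tss_tol = 1000L, gc_tol = 0.05) {
  pr <- set$pairs
  if (!nrow(pr)) return(logical(0))
  ica <- match(pr$case_id, cases$id)
  ipo <- match(pr$control_id, pool$id)
  stopifnot(!anyNA(ica), !anyNA(ipo))
  d_case <- dist_to_nearest_tss(cases[ica, , drop = FALSE], genes)
  d_ctrl <- dist_to_nearest_tss(pool[ipo, , drop = FALSE], genes)
  ok <- abs(cases$af[ica] - pool$af[ipo]) < af_tol
  ok <- ok & !duplicated(pr$control_id)
  if (set$scheme == "random_tss") {
    ok <- ok & d_ctrl <= tss_window
  } else {
    ok <- ok & abs(d_case - d_ctrl) <= tss_tol
    if (!is.null(ld) && nrow(ld)) {
      r2 <- new.env(parent = emptyenv())
      for (i in seq_len(nrow(ld))) {
        assign(paste(ld$snp_a[i], ld$snp_b[i], sep = "\r"), ld$r[i]^2, envir = r2)
        assign(paste(ld$snp_b[i], ld$snp_a[i], sep = "\r"), ld$r[i]^2, envir = r2)
      }
      look <- function(a, b) {
        k <- paste(a, b, sep = "\r")
        if (exists(k, envir = r2, inherits = FALSE)) get(k, envir = r2) else 0
      }
      adj <- high_ld_adjacency(ld, r2_max)
      for (j in seq_len(nrow(pr))) {
        cid <- pr$case_id[j]; ctl <- pr$control_id[j]
        if (look(ctl, cid) > r2_max) ok[j] <- FALSE
        for (p in adj_get(adj, cid)) {
          if (ctl == p || look(ctl, p) > r2_max) ok[j] <- FALSE
        }
      }
    }
    if (!is.null(gc) || !is.null(seqs)) {
      if (is.null(gc)) {
        gc <- c(setNames(gc_window(cases, seqs), cases$id),
                setNames(gc_window(pool, seqs), pool$id))
      }
      ok <- ok & abs(gc[pr$case_id] - gc[pr$control_id]) <= gc_tol
    }
  }
  unname(ok)
}

#' Write a matched control set as TSV
#'
#' Columns: case_id, control_id, scheme, af_case, af_control,
#' dist_tss_case, dist_tss_control.
#'
#' @param set a `matched_controls` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_controls <- function(set, path) {
  out <- set$pairs
  out$scheme <- set$scheme
  out <- out[c("case_id", "control_id", "scheme", "af_case", "af_control",
               "dist_tss_case", "dist_tss_control")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
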