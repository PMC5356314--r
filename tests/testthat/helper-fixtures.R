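# Small in-code fixtures shared across test files.

# a peak track from a compact spec: list of c(start, end, signal, summit)
make_track <- function(mark, rows, cell_type = "CT1", chrom = "chr1") {
  iv <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(chrom = chrom, start = r[1], end = r[2], signal = r[3],
                 summit_offset = r[4], stringsAsFactors = FALSE)
    }))
  } else {
    regpot:::empty_intervals()
  }
  regpot:::new_peak_track(mark, cell_type, iv)
}

make_variants <- function(pos, chrom = "chr1", af = NULL, gwas_p = NA_real_,
                          prefix = "rs") {
  n <- length(pos)
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), af = numeric(0),
                      gwas_p = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = chrom, pos = as.integer(pos),
    id = sprintf("%s%03d", prefix, seq_len(n)),
    af = if (is.null(af)) round(seq(0.1, 0.9, length.out = n), 4) else af,
    gwas_p = gwas_p, stringsAsFactors = FALSE
  )
}

# brute-force per-base membership oracle: is 1-based pos inside any
# 0-based half-open interval?
brute_force_hit <- function(pos, starts, ends) {
  if (!length(starts)) return(FALSE)
  covered <- unlist(mapply(function(s, e) seq.int(s, e - 1L), starts, ends,
                           SIMPLIFY = FALSE))
  (pos - 1L) %in% covered # 1-based position p occupies 0-based base p-1
}

# independent Simes oracle
simes_p <- function(p) min(length(p) * sort(p) / seq_along(p))

# planted-effect logistic fixture with known coefficients
make_logit_fixture <- function(n, alpha, beta, seed) {
  set.seed(seed)
  k <- length(beta)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, names(beta)))
  bin <- seq_len(k) %% 2L == 1L
  X[, bin] <- rbinom(n * sum(bin), 1L, 0.4)
  y <- rbinom(n, 1L, plogis(alpha + drop(X %*% beta)))
  list(X = X, y = y, alpha = alpha, beta = beta)
}
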