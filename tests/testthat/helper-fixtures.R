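# shared helpers: tiny builders and independent oracles

mk_gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0))
}

write_tree_file <- function(edges, path = tempfile(fileext = ".txt")) {
  writeLines(paste(edges$parent, edges$child), path)
  path
}

tiny_tree <- function() {
  cell_tree(data.frame(parent = c("HSC", "HSC", "CMP", "CMP"),
                       child = c("CMP", "CLP", "MEP", "GMP")))
}

# small, fast fixture for unit tests (13 cell types, ~700 cCREs)
small_fixture <- function(seed = 11L, dir = tempfile("fx"), ...) {
  # enough noise ISs that the top-5% size exclusion covers the 5 planted
  # outliers, as in the method's intended regime (many sparse ISs)
  cfg <- fixture_config(abundances = c(300L, 150L, 80L, 60L, 40L),
                        n_noise_singletons = 120L, n_background = 50L,
                        seed = seed, ...)
  generate_fixture(cfg, dir)
}

# brute-force sweep-line union of intervals; returns merged 0-based intervals
# (strict >0 bp overlap merge, book-ended intervals kept separate)
sweep_merge <- function(chrom, start0, end0) {
  out <- NULL
  for (ch in sort(unique(chrom))) {
    i <- chrom == ch
    o <- order(start0[i], end0[i])
    s <- start0[i][o]; e <- end0[i][o]
    cs <- s[1L]; ce <- e[1L]
    for (j in seq_along(s)[-1L]) {
      if (s[j] < ce) {          # shares >= 1 bp
        ce <- max(ce, e[j])
      } else {
        out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
        cs <- s[j]; ce <- e[j]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# independent MVN log-density (full constant), for the QDA oracle
mvn_logpdf <- function(x, mu, sigma) {
  d <- length(mu)
  -0.5 * d * log(2 * pi) - 0.5 * determinant(sigma, logarithm = TRUE)$modulus -
    0.5 * drop(t(x - mu) %*% solve(sigma) %*% (x - mu))
}

# exhaustive four-rule dominant-state oracle (independent implementation)
oracle_dominant_state <- function(cs, ce, bs, be, st,
                                  quiescent = c("0", "Q", "quiescent")) {
  ov <- pmin(be, ce) - pmax(bs, cs)
  keep <- ov > 0
  if (!any(keep)) return(quiescent[1L])
  bs <- bs[keep]; be <- be[keep]; st <- st[keep]
  labs <- unique(st)
  non_q <- labs[!(labs %in% quiescent)]
  elig <- if (length(non_q) > 0L) non_q else labs
  score <- lapply(elig, function(s) {
    i <- st == s
    clip_lo <- pmax(bs[i], cs); clip_hi <- pmin(be[i], ce)
    cov <- sum(clip_hi - clip_lo)
    u_lo <- max(min(bs[i]), cs); u_hi <- min(max(be[i]), ce)
    mid <- (u_lo + u_hi) / 2
    list(prop = cov / (ce - cs), dist = abs(mid - (cs + ce) / 2),
         bp = sum(be[i] - bs[i]))
  })
  names(score) <- elig
  best <- elig
  p <- vapply(score[best], `[[`, numeric(1), "prop")
  best <- best[p == max(p)]
  if (length(best) > 1L) {
    dd <- vapply(score[best], `[[`, numeric(1), "dist")
    best <- best[dd == min(dd)]
  }
  if (length(best) > 1L) {
    bp <- vapply(score[best], `[[`, numeric(1), "bp")
    best <- best[bp == max(bp)]
  }
  sort(best)[1L]
}

# dictionary-based Shannon entropy recount (independent of shannon_entropy)
oracle_entropy <- function(map, N, M, col_offset = 0L) {
  counts <- new.env(hash = TRUE)
  n_win <- nrow(map) - N + 1L
  for (t in seq_len(n_win)) {
    key <- paste(as.vector(t(map[t:(t + N - 1L),
                                 (col_offset + 1L):(col_offset + M),
                                 drop = FALSE])), collapse = "")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  p <- unlist(as.list(counts)) / n_win
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
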