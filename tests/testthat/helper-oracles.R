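# Independent oracles used across the suite. These deliberately take a
# different implementation route from the package (seqinr translation,
# direct permutation recursion, Mann-Whitney U counting) so that
# agreement is informative.

# all orderings of a vector, as a list (fresh recursion, no shared code)
allOrderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in allOrderings(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

aaOf <- function(codon) {
  toupper(seqinr::translate(strsplit(codon, "")[[1]]))
}

# brute-force Nei-Gojobori pathway averaging for one codon pair
ngPairOracle <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- list()
  clean <- list()
  for (ord in allOrderings(pos)) {
    cur <- a
    ns <- 0; nn <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      if (aaOf(paste(cur, collapse = "")) ==
          aaOf(paste(nxt, collapse = ""))) ns <- ns + 1 else nn <- nn + 1
      if (aaOf(paste(nxt, collapse = "")) == "*" && any(nxt != b))
        hit_stop <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(ns, nn)
    if (!hit_stop) clean[[length(clean) + 1L]] <- c(ns, nn)
  }
  use <- if (length(clean)) clean else paths
  m <- do.call(rbind, use)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# exact rank-sum p-value by Mann-Whitney U enumeration over index subsets
uEnumOracle <- function(x, y, alternative) {
  pooled <- c(x, y)
  N <- length(pooled)
  n <- length(x)
  r <- rank(pooled)
  Wobs <- sum(r[seq_len(n)])
  subsets <- utils::combn(N, n)
  Ws <- apply(subsets, 2L, function(idx) sum(r[idx]))
  C <- length(Ws)
  switch(alternative,
    less = sum(Ws <= Wobs + 1e-9) / C,
    greater = sum(Ws >= Wobs - 1e-9) / C,
    two.sided = min(1, 2 * min(sum(Ws <= Wobs + 1e-9) / C,
                               sum(Ws >= Wobs - 1e-9) / C)))
}

# per-pair Nei-Gojobori pN/pS counts over a codon alignment segment,
# written directly from the definitions (site counts by enumeration)
ngSegmentOracle <- function(seqs, cols) {
  siteCounts <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (i in 1:3) {
      syn <- 0; tot <- 0
      for (nt in setdiff(c("A", "C", "G", "T"), ch[i])) {
        alt <- ch; alt[i] <- nt
        aa <- aaOf(paste(alt, collapse = ""))
        if (aa == "*") next
        tot <- tot + 1
        if (aa == aaOf(codon)) syn <- syn + 1
      }
      if (tot > 0) s <- s + syn / tot
    }
    c(s, 3 - s)
  }
  tot <- c(0, 0, 0, 0) # sd, nd, ss, ns
  ns <- length(seqs)
  for (i in seq_len(ns - 1L)) {
    for (j in seq(i + 1L, ns)) {
      for (k in cols) {
        ca <- substr(seqs[i], 3 * k - 2, 3 * k)
        cb <- substr(seqs[j], 3 * k - 2, 3 * k)
        if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
        if (aaOf(ca) == "*" || aaOf(cb) == "*") next
        si <- siteCounts(ca); sj <- siteCounts(cb)
        tot[3] <- tot[3] + (si[1] + sj[1]) / 2
        tot[4] <- tot[4] + (si[2] + sj[2]) / 2
        if (ca != cb) {
          d <- ngPairOracle(ca, cb)
          tot[1] <- tot[1] + d[["syn"]]
          tot[2] <- tot[2] + d[["nonsyn"]]
        }
      }
    }
  }
  if (tot[1] == 0 || tot[3] == 0 || tot[4] == 0) return(NA_real_)
  (tot[2] / tot[4]) / (tot[1] / tot[3])
}

senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
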