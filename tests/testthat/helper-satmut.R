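# shared fixture builders (everything generated in code; no binary data)

library(data.table)

# apply a haplotype (token string) to a reference sequence; SNVs replace,
# 1-bp deletions remove, insertions insert before the position
apply_haplotype <- function(seq, tokens) {
  if (!nzchar(tokens)) return(seq)
  v <- satmut::parse_variant_tokens(tokens)
  v <- v[order(-position)]
  s <- strsplit(seq, NULL)[[1]]
  for (i in seq_len(nrow(v))) {
    p <- v$position[i] + 1L
    if (v$vclass[i] == "deletion_1bp") {
      s <- s[-p]
    } else if (v$vclass[i] == "insertion") {
      s <- append(s, strsplit(v$alt[i], NULL)[[1]], after = p - 1L)
    } else {
      s[p] <- v$alt[i]
    }
  }
  paste(s, collapse = "")
}

# tiny deterministic count table + assignment for design/fit tests
toy_count_fixture <- function() {
  assignment <- data.table(
    tag = sprintf("TAG%02d", 1:6),
    variants = c("", "", "", "5:A>G", "5:A>G", "5:A>G"),
    n_supporting_reads = 5L, disqualified = FALSE, reason = NA_character_)
  counts <- rbindlist(lapply(1:2, function(r)
    data.table(replicate = r, tag = assignment$tag,
               dna_count = c(10, 20, 40, 10, 20, 40),
               rna_count = c(10, 20, 40, 20, 40, 80))))
  list(assignment = assignment, counts = counts)
}

# independent OLS oracle: base-R qr on the dense system
ols_oracle <- function(X, y) {
  qr.coef(qr(as.matrix(X)), y)
}

# brute-force deltaSVM oracle by direct k-mer enumeration (literal lookup
# only; absent k-mers are zero)
delta_svm_oracle <- function(seq, pos, alt, weights, k) {
  L <- nchar(seq)
  starts <- max(0, pos - k + 1):min(L - k, pos)
  look <- function(s) {
    w <- weights[substring(s, starts + 1, starts + k)]
    w[is.na(w)] <- 0
    mean(w)
  }
  altseq <- paste0(substr(seq, 1, pos), alt, substr(seq, pos + 2, L))
  look(seq) - look(altseq)
}

# exhaustive PWM window scores on both strands
scan_pwm_oracle <- function(seq, mat) {
  rc <- function(x) chartr("ACGT", "TGCA",
    paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
  w <- ncol(mat); L <- nchar(seq)
  score1 <- function(s) sum(vapply(seq_len(nchar(s)), function(i)
    mat[match(substr(s, i, i), c("A", "C", "G", "T")), i], numeric(1)))
  out <- list()
  for (st in 0:(L - w)) {
    win <- substr(seq, st + 1, st + w)
    out[[length(out) + 1]] <- data.table(start = st, strand = "+",
                                         raw_score = score1(win))
    out[[length(out) + 1]] <- data.table(start = st, strand = "-",
                                         raw_score = score1(rc(win)))
  }
  rbindlist(out)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
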