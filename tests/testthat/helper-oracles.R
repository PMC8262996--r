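# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (double loops, enumeration, separate sampling code) so
# they cannot share bugs with the package implementations they check.

# Exhaustive double-loop betaMNTD on raw count vectors.
oracle_beta_mntd <- function(x_i, x_j, D, transform = "log1p") {
  g <- function(v) if (transform == "log1p") log1p(v) else v
  wi <- g(x_i); wi[x_i == 0] <- 0; wi <- wi / sum(wi)
  wj <- g(x_j); wj[x_j == 0] <- 0; wj <- wj / sum(wj)
  pi <- which(x_i > 0); pj <- which(x_j > 0)
  s1 <- 0
  for (a in pi) {
    best <- Inf
    for (b in pj) best <- min(best, D[a, b])
    s1 <- s1 + wi[a] * best
  }
  s2 <- 0
  for (b in pj) {
    best <- Inf
    for (a in pi) best <- min(best, D[b, a])
    s2 <- s2 + wj[b] * best
  }
  unname(0.5 * (s1 + s2))
}

# All permutations of 1..n (recursive enumeration).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Naive Raup-Crick for one pair: separate implementation of the null
# assembler (explicit weighted sampling loop, not rc_null_community).
oracle_raup_crick_pair <- function(counts, i, j, n_rand, seed,
                                   tie_weight = 0.5) {
  occ <- colSums(counts > 0)
  ab <- colSums(counts)
  bc <- function(a, b) sum(abs(a - b)) / sum(a + b)
  obs <- bc(counts[i, ], counts[j, ])
  set.seed(seed)
  draw_null <- function(s) {
    rich <- sum(counts[s, ] > 0)
    depth <- sum(counts[s, ])
    chosen <- integer(0)
    avail <- which(occ > 0)
    p <- occ[avail]
    for (k in seq_len(rich)) {
      pick <- sample(seq_along(avail), 1, prob = p)
      chosen <- c(chosen, avail[pick])
      avail <- avail[-pick]
      p <- p[-pick]
    }
    x <- numeric(ncol(counts))
    x[chosen] <- 1
    extra <- depth - rich
    if (extra > 0) {
      more <- sample(chosen, extra, replace = TRUE, prob = ab[chosen])
      tb <- table(more)
      x[as.integer(names(tb))] <- x[as.integer(names(tb))] + as.integer(tb)
    }
    x
  }
  less <- 0; ties <- 0
  for (r in seq_len(n_rand)) {
    nb <- bc(draw_null(i), draw_null(j))
    if (nb < obs - 1e-12) less <- less + 1
    else if (abs(nb - obs) <= 1e-12) ties <- ties + 1
  }
  2 * ((less + tie_weight * ties) / n_rand - 0.5)
}

# Random valid OTU table.
random_table <- function(n_samples, n_otus, lambda = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus)
  m[rowSums(m) == 0, 1] <- 1L
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("otu%03d", seq_len(n_otus)))
  otu_table(m)
}

# Small fixed 4-tip tree used in several hand-computed examples.
tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")

# Metadata skeleton for a host x site x replicate layout.
toy_meta <- function(hosts = c("A", "B"), sites = c("1", "2"), reps = 2) {
  grid <- expand.grid(rep = seq_len(reps), site = sites, host = hosts,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%s_%d", grid$host, grid$site, grid$rep),
    host_species = grid$host,
    site = grid$site,
    latitude = 25 + 2 * as.integer(factor(grid$site)),
    longitude = 100 + as.integer(factor(grid$site)),
    mat = 20 - as.integer(factor(grid$site)),
    map_mm = 1000 + 10 * as.integer(factor(grid$site)),
    haplotype = NA_character_
  )
}
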