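# Shared fixtures, all built in code at test time.

# tiny single-chromosome genome with both telomeres, an STE and two genes
tiny_genome <- function(L = 50000, tel = 2000) {
  feats <- data.frame(
    chromosome = "chr1",
    start = c(0, L - tel, tel, 12000, 30000, L / 2 - 1000),
    end = c(tel, L, tel + 3000, 15000, 33000, L / 2 + 1000),
    strand = c(".", ".", ".", "+", "-", "."),
    class = c("telomere_repeat", "telomere_repeat", "STE",
              "gene", "gene", "centromere"),
    name = c("telL", "telR", "STE1", "gA", "gB", "cen"),
    stringsAsFactors = FALSE)
  genome_model("target", data.frame(name = "chr1", length = L), feats)
}

# two-chromosome genome used for hand-built contact matrices
two_chrom_genome <- function(L = c(40000, 30000), res = 10000) {
  chroms <- data.frame(name = c("chrA", "chrB"), length = L)
  feats <- data.frame(
    chromosome = rep(c("chrA", "chrB"), each = 2),
    start = c(0, L[1] - 2000, 0, L[2] - 2000),
    end = c(2000, L[1], 2000, L[2]),
    strand = ".",
    class = "telomere_repeat",
    name = c("A-telL", "A-telR", "B-telL", "B-telR"),
    stringsAsFactors = FALSE)
  genome_model("target", chroms, feats)
}

# random symmetric positive matrix as a contact_matrix
random_contact_matrix <- function(n_bins_per_chrom = c(4, 3), res = 10000,
                                  seed = 1) {
  set.seed(seed)
  n <- sum(n_bins_per_chrom)
  M <- matrix(stats::runif(n * n, 0.5, 5), n, n)
  M <- (M + t(M)) / 2
  chroms <- data.frame(name = paste0("c", seq_along(n_bins_per_chrom)),
                       length = n_bins_per_chrom * res)
  contact_matrix(M, res, chromosomes = chroms)
}

# brute-force per-position fragment overlap count
brute_coverage <- function(fragments, L) {
  vapply(seq_len(L) - 1L, function(pos)
    sum(fragments$start <= pos & fragments$end > pos), numeric(1))
}

# brute-force connected components over the <= radius distance graph
brute_foci <- function(points, radius) {
  n <- nrow(points)
  if (n == 0) return(0L)
  adj <- as.matrix(stats::dist(points)) <= radius
  seen <- rep(FALSE, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  k
}

# independent exact Mann-Whitney oracle: U counted pairwise, p by full
# enumeration of label assignments over the pooled multiset
brute_mw <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  U_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u <- U_of(x, y)
  mu <- n1 * n2 / 2
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(ii) U_of(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  p <- switch(alternative,
              two.sided = mean(abs(Us - mu) >= abs(u - mu) - eps),
              greater = mean(Us >= u - eps),
              less = mean(Us <= u + eps))
  list(U = u, p = p)
}

# hand-built cell record: 2 SPBs at +-d/2 on x, plus k well-separated foci
synthetic_cell <- function(cell_id, spindle, n_foci, condition = "wt") {
  pts <- cbind(seq_len(n_foci) * 2.5, 0, 0)  # >= 2.5 um apart
  data.frame(cell_id = cell_id,
             object_type = c("spb", "spb", rep("telomere", n_foci)),
             x = c(-spindle / 2, spindle / 2, pts[, 1]),
             y = c(0, 0, pts[, 2]),
             z = c(0, 0, pts[, 3]),
             stage_truth = NA_character_,
             true_foci = n_foci,
             condition = condition,
             stringsAsFactors = FALSE)
}
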