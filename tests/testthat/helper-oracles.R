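# Exhaustive normalized cross-correlation search in plain R: the independent
# oracle against which the tracker's localizer is checked. Returns the best
# integer box-origin offset (dx, dy) over the full search window.
ncc_oracle_argmax <- function(img, templ, x0, y0, radius) {
  th <- nrow(templ); tw <- ncol(templ)
  h <- nrow(img); w <- ncol(img)
  tv <- as.vector(templ)
  best <- -Inf; best_off <- c(NA, NA)
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      ox <- x0 + dx; oy <- y0 + dy
      if (ox < 0 || oy < 0 || ox + tw > w || oy + th > h) next
      patch <- as.vector(img[(oy + 1):(oy + th), (ox + 1):(ox + tw)])
      r <- suppressWarnings(stats::cor(patch, tv))
      if (is.na(r)) r <- 0
      if (abs(r) > best) {
        best <- abs(r)
        best_off <- c(dx, dy)
      }
    }
  }
  best_off
}

# Does a compact letter display reproduce the pairwise significance relation?
letters_match_pmatrix <- function(lets, p, alpha = 0.05) {
  k <- nrow(p)
  chars <- strsplit(lets, "")
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- length(intersect(chars[[i]], chars[[j]])) > 0
      if (share != (p[i, j] >= alpha)) return(FALSE)
    }
  }
  TRUE
}

# Brute-force minimum clique cover of the non-significance graph on n nodes:
# the smallest number of letters any correct display could use.
min_clique_cover <- function(ns_adj) {
  n <- nrow(ns_adj)
  subsets <- list()
  for (m in 1:(2^n - 1)) {
    members <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      prs <- utils::combn(members, 2)
      ok <- all(ns_adj[t(prs)])
    }
    if (ok) subsets[[length(subsets) + 1]] <- members
  }
  # greedy-free exact search over numbers of cliques
  for (size in 1:n) {
    combos <- utils::combn(length(subsets), size, simplify = FALSE)
    for (cmb in combos) {
      cover <- unique(unlist(subsets[cmb]))
      if (length(cover) == n) {
        # every non-significant pair must lie inside some chosen clique
        all_pairs_ok <- TRUE
        for (i in seq_len(n - 1)) {
          for (j in (i + 1):n) {
            if (ns_adj[i, j]) {
              inside <- any(vapply(subsets[cmb], function(s) all(c(i, j) %in% s), logical(1)))
              if (!inside) { all_pairs_ok <- FALSE; break }
            }
          }
          if (!all_pairs_ok) break
        }
        if (all_pairs_ok) return(size)
      }
    }
  }
  n
}

# random symmetric p-value matrix with unit diagonal
random_pmatrix <- function(k, seed) {
  set.seed(seed)
  p <- matrix(1, k, k)
  vals <- stats::runif(k * (k - 1) / 2)
  p[upper.tri(p)] <- vals
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  dimnames(p) <- list(paste0("g", 1:k), paste0("g", 1:k))
  p
}
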