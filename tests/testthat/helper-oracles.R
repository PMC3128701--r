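## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately naive re-derivations (enumeration, per-voxel loops) kept
## separate from the package's implementations.

tinyGrid <- function(n = 6L, vox = 2) voxelGrid(rep(n, 3L), vox)

## random sparse mask by direct voxel sampling (independent of the
## package's ellipsoid generator)
randomMask <- function(id, grid, density = 0.2) {
  nvox <- prod(gridDims(grid))
  lesionMask(id, grid, sample(nvox, max(1L, round(density * nvox))))
}

## --- brute-force per-voxel overlap count -------------------------------
bruteOverlapCounts <- function(masks) {
  grid <- masks[[1]]@grid
  nvox <- prod(gridDims(grid))
  vapply(seq_len(nvox), function(v)
    sum(vapply(masks, function(m) v %in% lesionIndices(m), logical(1))),
    integer(1))
}

## --- brute-force coverage-pattern grouping -----------------------------
## returns a list keyed by membership bit-vector string: voxel index sets
brutePartition <- function(masks, minOverlap) {
  nvox <- prod(gridDims(masks[[1]]@grid))
  member <- vapply(masks, function(m) seq_len(nvox) %in% lesionIndices(m),
                   logical(nvox))
  counts <- rowSums(member)
  keep <- which(counts >= minOverlap)
  keys <- apply(member[keep, , drop = FALSE], 1,
                function(r) paste(as.integer(r), collapse = ""))
  split(keep, keys)
}

## --- exact permutation enumeration for the rank-sum test ---------------
enumRankSumP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

## --- exact sign-flip enumeration for the signed-rank test --------------
enumSignedRankP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(ws <= wObs), mean(ws >= wObs)))
}

## --- textbook step-down Holm -------------------------------------------
bruteHolm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  rejectedSorted <- logical(m)
  for (i in seq_len(m)) {
    ok <- all(p[ord][seq_len(i)] <= alpha / (m - seq_len(i) + 1))
    rejectedSorted[i] <- ok
    if (!ok) break
  }
  rejected <- logical(m)
  rejected[ord] <- rejectedSorted
  rejected
}

## --- trial-stream construction helpers ---------------------------------
streamRow <- function(t, kind, target = FALSE, side = NA_character_) {
  data.frame(session_id = "s", task = "test", t_ms = t, kind = kind,
             is_pm_target = target, correct_side = side,
             stringsAsFactors = FALSE)
}

buildStream <- function(...) {
  df <- do.call(rbind, list(...))
  df[order(df$t_ms), , drop = FALSE]
}

## ongoing stream with explicit per-trial (response side, rt) pairs
ongoingStream <- function(sides, respSides, rts, spacing = 2000) {
  rows <- list()
  for (i in seq_along(sides)) {
    t0 <- (i - 1) * spacing
    rows[[length(rows) + 1L]] <- streamRow(t0, "stimulus_on",
                                           side = sides[i])
    if (!is.na(respSides[i]))
      rows[[length(rows) + 1L]] <- streamRow(t0 + rts[i], respSides[i])
  }
  do.call(rbind, rows)
}
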