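# Shared fixtures: everything is generated in code, no binary files.

fixtureCompounds <- function() defaultCompounds()

# random admissible label volume over the default label alphabet
randomLabelMatrix <- function(dims = c(4, 6, 5), seed = 1,
                              voxelEdge = 0.028) {
  set.seed(seed)
  lab <- array(sample(c(0L, 1L, 31L, 200L), prod(dims), replace = TRUE),
               dims)
  VoxelMatrix(lab, voxelEdge)
}

# independent 6-connectivity check: BFS over the voxel coordinates of one
# label; TRUE iff they form a single connected component
isSingleCluster6 <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  if (nrow(idx) == 1L) return(TRUE)
  key <- function(v) paste(v, collapse = ",")
  todo <- key(idx[1L, ])
  seen <- new.env(parent = emptyenv())
  assign(todo, TRUE, envir = seen)
  all_keys <- apply(idx, 1L, key)
  queue <- list(idx[1L, ])
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (i in seq_len(6)) {
      nb <- cur + offs[i, ]
      k <- key(nb)
      if (k %in% all_keys && !exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  length(ls(seen)) == nrow(idx)
}

# one-line independent oracles used across tests
oracleF1 <- function(r, t) 100 * sum(abs(r - t)) / sum(r)
oracleF2 <- function(r, t)
  50 * log10(100 / sqrt(1 + mean((r - t)^2)))
oracleTabletPorosity <- function(mApi, mEx, rhoApi, rhoEx, D, h)
  (1 - 1000 * (mApi / rhoApi + mEx / rhoEx) /
     (pi * (D / 2)^2 * h)) * 100
oracleExPorosity <- function(S, phiT, phiI, vx, vApi, vEx, h)
  S * (phiT - phiI) * vx * (vApi + vEx) * (1 + 0.01 * phiT) / (h * vEx)
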