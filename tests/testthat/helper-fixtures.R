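# Shared fixtures, generated in code. Small phantoms are cached per session.

local_cache <- new.env()

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

thigh64 <- function(seed = 3) cached(paste0("thigh64_", seed),
  generate_slice(phantom_config("thigh", image_size = 64, seed = seed)))

leg64 <- function(seed = 3) cached(paste0("leg64_", seed),
  generate_slice(phantom_config("leg", image_size = 64, seed = seed)))

# Independent flood-fill connected components (queue-based), the oracle for
# the Rcpp labelling and for clean_mask.
flood_components <- function(mask, connectivity = 8) {
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
        if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask)) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Brute-force area opening+closing oracle built on flood_components.
clean_mask_oracle <- function(labels, thr = 4, connectivity = 8) {
  hole_conn <- if (connectivity == 8) 4 else 8
  for (cl in sort(setdiff(unique(as.vector(labels)), 0L))) {
    comp <- flood_components(labels == cl, connectivity)
    for (k in seq_len(max(comp)))
      if (sum(comp == k) < thr) labels[comp == k] <- 0L
    holes <- flood_components(labels != cl, hole_conn)
    if (max(holes) > 0)
      for (k in seq_len(max(holes)))
        if (sum(holes == k) < thr) labels[holes == k] <- cl
  }
  labels
}

# Exhaustive nearest/second-nearest distinct-class distances.
border_term_oracle <- function(labels, w0 = 10, sigma = 7) {
  classes <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(classes) < 2) return(matrix(0, nrow(labels), ncol(labels)))
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(0, nr, nc)
  pts <- lapply(classes, function(cl) which(labels == cl, arr.ind = TRUE))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d <- vapply(pts, function(p)
      sqrt(min((p[, 1] - i)^2 + (p[, 2] - j)^2)), 0)
    d <- sort(d)
    out[i, j] <- w0 * exp(-(d[1] + d[2])^2 / (2 * sigma^2))
  }
  out
}
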