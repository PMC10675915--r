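# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own C++ primitives.

# Brute-force connected-component labeling by flood fill.
# connectivity: 1 = faces, 2 = faces+edges, 3 = full neighborhood.
# Labels assigned in linear-index (x fastest) order of first voxel.
label_oracle <- function(arr, connectivity = 2) {
  dm <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) >= 1 & rowSums(abs(offs)) <= connectivity, ,
               drop = FALSE]
  lab <- array(0L, dm)
  nxt <- 0L
  for (p in which(arr == 1)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    stack <- p
    lab[p] <- nxt
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (q - 1) %% dm[1]
      j <- ((q - 1) %/% dm[1]) %% dm[2]
      k <- (q - 1) %/% (dm[1] * dm[2])
      for (m in seq_len(nrow(offs))) {
        ii <- i + offs[m, 1]; jj <- j + offs[m, 2]; kk <- k + offs[m, 3]
        if (ii < 0 || jj < 0 || kk < 0 ||
            ii >= dm[1] || jj >= dm[2] || kk >= dm[3]) next
        qq <- 1 + ii + dm[1] * (jj + dm[2] * kk)
        if (arr[qq] == 1 && lab[qq] == 0L) {
          lab[qq] <- nxt
          stack <- c(stack, qq)
        }
      }
    }
  }
  lab
}

# Double-loop pairwise distances (cm) between rows of a centers matrix (mm).
pairwise_oracle <- function(centers) {
  n <- nrow(centers)
  out <- NULL
  if (n < 2) return(out)
  for (a in 1:(n - 1))
    for (b in (a + 1):n)
      out <- rbind(out, c(a, b, sqrt(sum((centers[a, ] - centers[b, ])^2)) / 10))
  out
}

# Textbook Pearson correlation from sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Small binary sphere mask volume.
sphere_mask <- function(dm = c(16, 16, 16), spacing = c(2, 2, 2),
                        center_mm = spacing * (dm - 1) / 2, radius_mm = 10) {
  idx <- as.matrix(expand.grid(0:(dm[1] - 1), 0:(dm[2] - 1), 0:(dm[3] - 1)))
  w <- sweep(idx, 2, spacing, `*`)
  inside <- rowSums(sweep(w, 2, center_mm, `-`)^2) <= radius_mm^2
  scalar_volume(array(as.numeric(inside), dm), spacing, modality = "MASK")
}

# Number of foreground voxels with at least one 6-neighbor outside the mask.
boundary_voxel_count <- function(arr) {
  dm <- dim(arr)
  pad <- array(0, dm + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- arr
  cnt <- 0
  for (p in which(pad == 1)) {
    i <- (p - 1) %% (dm[1] + 2)
    j <- ((p - 1) %/% (dm[1] + 2)) %% (dm[2] + 2)
    k <- (p - 1) %/% ((dm[1] + 2) * (dm[2] + 2))
    nb <- c(pad[i, j + 1, k + 1], pad[i + 2, j + 1, k + 1],
            pad[i + 1, j, k + 1], pad[i + 1, j + 2, k + 1],
            pad[i + 1, j + 1, k], pad[i + 1, j + 1, k + 2])
    if (any(nb == 0)) cnt <- cnt + 1
  }
  cnt
}

dice_coefficient <- function(a, b) {
  2 * sum(a > 0 & b > 0) / (sum(a > 0) + sum(b > 0))
}

# A small, fast cohort configuration used by unit tests (half-size grid).
test_config <- function(...) {
  cohort_config(grid_shape = c(48L, 48L, 120L), spacing_mm = c(4, 4, 4), ...)
}

# CT volume whose torso fat percentage is exactly `pct` (out of 100 voxels
# of soft tissue/adipose in a compact block), plus the matching body mask.
exact_fat_ct <- function(pct) {
  dm <- c(10, 10, 4)
  vals <- array(-1000, dm)
  block <- matrix(40, 10, 10)
  block[seq_len(pct)] <- -100
  for (k in 2:3) vals[, , k] <- block
  ct <- scalar_volume(vals, c(4, 4, 4), modality = "CT_HU")
  body <- scalar_volume(array(as.numeric(vals > -500), dm), c(4, 4, 4),
                        modality = "MASK")
  list(ct = ct, body = body)
}
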