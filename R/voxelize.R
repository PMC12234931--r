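# Partial-volume voxelization of implicit solids.
#
# A solid is described by an indicator function over world coordinates (mm).
# Voxels whose 8 corners and centre agree on membership get weight 0 or 1;
# only the disagreeing boundary voxels are supersampled. This keeps the cost
# proportional to the surface, so fine grids stay tractable.

# f_inside: function(x, y, z) -> logical, vectorized over equal-length vectors.
voxelize_solid <- function(f_inside, dim, spacing, origin, supersample = 3L) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  cx <- origin[1] + (seq_len(nx) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(ny) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(nz) - 1) * spacing[3]

  # corner lattice: (n+1) planes per axis at voxel boundaries
  bx <- c(cx - spacing[1] / 2, cx[nx] + spacing[1] / 2)
  by <- c(cy - spacing[2] / 2, cy[ny] + spacing[2] / 2)
  bz <- c(cz - spacing[3] / 2, cz[nz] + spacing[3] / 2)
  corner <- array(
    f_inside(
      rep(bx, times = (ny + 1) * (nz + 1)),
      rep(rep(by, each = nx + 1), times = nz + 1),
      rep(bz, each = (nx + 1) * (ny + 1))
    ),
    dim = c(nx + 1, ny + 1, nz + 1)
  )

  # per-voxel count of inside corners (0..8)
  csum <- array(0L, dim)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    csum <- csum + corner[(1:nx) + di, (1:ny) + dj, (1:nz) + dk]
  }
  centre_in <- array(
    f_inside(
      rep(cx, times = ny * nz),
      rep(rep(cy, each = nx), times = nz),
      rep(cz, each = nx * ny)
    ),
    dim = dim
  )

  w <- array(0, dim)
  w[csum == 8L & centre_in] <- 1

  # a voxel is boundary if its own samples disagree, or if any face
  # neighbour's centre disagrees with its own (catches solids grazing a
  # face without touching any corner or the centre)
  neighbour_differs <- array(FALSE, dim)
  for (ax in 1:3) for (dd in c(-1L, 1L)) {
    idx_src <- lapply(dim, seq_len)
    idx_dst <- idx_src
    n <- dim[ax]
    if (dd == 1L) {
      idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n
    } else {
      idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1)
    }
    shifted <- do.call(`[`, c(list(centre_in), idx_src, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(centre_in), idx_dst, list(drop = FALSE)))
    tmp <- array(FALSE, dim)
    do.call(`[<-`, c(list(tmp), idx_dst, list(shifted != cur))) ->
      neighbour_differs_part
    neighbour_differs <- neighbour_differs | neighbour_differs_part
  }

  mixed <- which((csum > 0L & csum < 8L) | (csum == 8L & !centre_in) |
                   (csum == 0L & centre_in) | neighbour_differs)
  if (length(mixed)) {
    s <- as.integer(supersample)
    off <- (seq_len(s) - (s + 1) / 2) / s
    idx <- arrayInd(mixed, dim)
    px <- cx[idx[, 1]]; py <- cy[idx[, 2]]; pz <- cz[idx[, 3]]
    frac <- numeric(length(mixed))
    for (ox in off) for (oy in off) for (oz in off) {
      frac <- frac + f_inside(
        px + ox * spacing[1], py + oy * spacing[2], pz + oz * spacing[3]
      )
    }
    w[mixed] <- frac / s^3
  }
  w
}

# Grid just covering a centred solid of half-extents `half` (mm) plus margin.
centered_grid <- function(half, spacing, margin, min_dim = 8L) {
  spacing <- rep_len(spacing, 3L)
  dim <- pmax(ceiling((2 * (half + margin)) / spacing), min_dim)
  # centre the solid at world 0; origin places voxel centres symmetrically
  origin <- -(dim - 1) * spacing / 2
  list(dim = as.integer(dim), spacing = spacing, origin = origin)
}
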