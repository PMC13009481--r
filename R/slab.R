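#' Patch and thin-slab geometry
#'
#' Fixes how volumes are cut into network inputs and how outputs are
#' recombined. In-plane, low-resolution images are cropped into square
#' patches with a fixed overlap (64/16 for in-plane scale 2, 32/8 for scale
#' 4, matching high-resolution 128/32 patches); through-plane, `M` adjacent
#' slices form a thin slab mapped to network channels, with `M - 1`
#' overlapping slices between neighboring slabs. The output slab carries
#' `N = M * s_sl` slices for super-resolution (through-plane upsampling via
#' the channel dimension) or `N = M` for motion artifact reduction.
#'
#' @param sf A [scale_factor()]; the two in-plane components must be equal.
#' @param M Slices per input slab (odd, between 1 and 5).
#' @param hr_size,hr_overlap In-plane high-resolution patch size and overlap
#'   (defaults 128 and 32).
#' @param task `"srr"` or `"mar"`; determines `N`.
#' @param plane Label for the in-plane orientation (metadata only).
#' @return An object of class `patch_geometry`.
#' @export
patch_geometry <- function(sf = scale_factor(1, 1, 1), M = 1L,
                           hr_size = 128L, hr_overlap = 32L,
                           task = c("srr", "mar"),
                           plane = c("sagittal", "axial")) {
  task <- match.arg(task); plane <- match.arg(plane)
  stopifnot(inherits(sf, "scale_factor"))
  if (sf$s[1] != sf$s[2])
    stop("in-plane scale must be symmetric (s_fe == s_pe)", call. = FALSE)
  M <- as.integer(M)
  if (M %% 2L != 1L || M < 1L || M > 5L)
    stop("M must be odd and between 1 and 5", call. = FALSE)
  ip <- sf$s[1]
  if (hr_size %% ip != 0L || hr_overlap %% ip != 0L)
    stop("hr_size and hr_overlap must be divisible by the in-plane scale",
         call. = FALSE)
  N <- if (task == "srr") M * sf$s[3] else M
  structure(list(sf = sf, inplane_scale = ip, s_sl = if (task == "srr") sf$s[3] else 1L,
                 M = M, N = N,
                 hr_size = as.integer(hr_size), hr_overlap = as.integer(hr_overlap),
                 lr_size = as.integer(hr_size %/% ip),
                 lr_overlap = as.integer(hr_overlap %/% ip),
                 task = task, plane = plane),
            class = "patch_geometry")
}

# 0-based patch start positions covering a length-L axis with the given patch
# size and overlap; the final patch is snapped to end at the boundary.
patch_starts <- function(L, size, overlap) {
  if (size > L) stop("patch size ", size, " exceeds axis length ", L, call. = FALSE)
  stride <- size - overlap
  stopifnot(stride >= 1)
  st <- seq.int(0L, L - size, by = stride)
  if (st[length(st)] != L - size) st <- c(st, L - size)
  as.integer(st)
}

#' Enumerate thin slabs of a volume
#'
#' Slabs of `M` contiguous slices along the third axis at the given stride
#' (default 1, so neighbors share `M - 1` slices and every interior slice
#' appears in `M` slabs).
#'
#' @param v Numeric 3D array.
#' @param M Slices per slab (odd, `M <= dim(v)[3]`).
#' @param stride Slab stride (default 1).
#' @return List with `starts` (0-based start slices) and `slabs` (list of
#'   `H x W x M` arrays).
#' @export
extract_slabs <- function(v, M, stride = 1L) {
  assert_volume(v)
  D <- dim(v)[3]
  if (M > D) stop("M (", M, ") exceeds volume depth (", D, ")", call. = FALSE)
  starts <- seq.int(0L, D - M, by = stride)
  slabs <- lapply(starts, function(s) v[, , (s + 1):(s + M), drop = FALSE])
  list(starts = as.integer(starts), slabs = slabs)
}

# Number of stride-1 slabs containing slice i (0-based), closed form.
slab_coverage_count <- function(i, D, M) {
  pmin(i, M - 1, D - 1 - i, D - M) + 1
}

#' Extract paired low/high-resolution training patches
#'
#' Cuts matched patch pairs: in-plane grids with the geometry's size/overlap
#' (low-resolution grid positions times the in-plane scale give the
#' high-resolution positions), and through-plane thin slabs of `M` input
#' slices paired with `N = M * s_sl` output slices.
#'
#' @param hr High-resolution volume.
#' @param lr Low-resolution volume; `dim(hr)` must equal `dim(lr)` times the
#'   scale factor componentwise (for MAR both volumes have equal shape).
#' @param geom A [patch_geometry()].
#' @return List of pairs, each `list(lr = array, hr = array, pos = c(i, j, s))`
#'   with 0-based low-resolution grid positions.
#' @export
extract_patch_pairs <- function(hr, lr, geom) {
  assert_volume(hr); assert_volume(lr)
  stopifnot(inherits(geom, "patch_geometry"))
  sc <- c(geom$inplane_scale, geom$inplane_scale, geom$s_sl)
  for (ax in 1:3) {
    if (dim(hr)[ax] != dim(lr)[ax] * sc[ax])
      stop("axis ", ax, ": hr dim ", dim(hr)[ax], " != lr dim ",
           dim(lr)[ax], " x scale ", sc[ax], call. = FALSE)
  }
  grid <- patch_grid(dim(lr), geom)
  lapply(grid, function(p) {
    hi <- p$pos * sc
    list(lr = lr[(p$pos[1] + 1):(p$pos[1] + geom$lr_size),
                 (p$pos[2] + 1):(p$pos[2] + geom$lr_size),
                 (p$pos[3] + 1):(p$pos[3] + geom$M), drop = FALSE],
         hr = hr[(hi[1] + 1):(hi[1] + geom$hr_size),
                 (hi[2] + 1):(hi[2] + geom$hr_size),
                 (hi[3] + 1):(hi[3] + geom$N), drop = FALSE],
         pos = p$pos)
  })
}

# All (i, j, s) 0-based low-resolution patch/slab positions for a LR shape.
patch_grid <- function(lr_dim, geom) {
  si <- patch_starts(lr_dim[1], geom$lr_size, geom$lr_overlap)
  sj <- patch_starts(lr_dim[2], geom$lr_size, geom$lr_overlap)
  ss <- seq.int(0L, lr_dim[3] - geom$M, by = 1L)
  out <- vector("list", length(si) * length(sj) * length(ss))
  n <- 0L
  for (s in ss) for (j in sj) for (i in si) {
    n <- n + 1L
    out[[n]] <- list(pos = c(i, j, s))
  }
  out
}

# Ownership intervals for in-plane tiling: each patch keeps its central
# region, with boundaries at the midpoint of the overlap between neighbors;
# edge patches keep their outer borders.
own_intervals <- function(starts, size, L) {
  k <- length(starts)
  lo <- integer(k); hi <- integer(k)
  for (t in seq_len(k)) {
    lo[t] <- if (t == 1L) 0L else (starts[t - 1L] + size + starts[t]) %/% 2L
    hi[t] <- if (t == k) L else (starts[t] + size + starts[t + 1L]) %/% 2L
  }
  list(lo = lo, hi = hi)
}

#' Stitch network output patches into candidate volumes
#'
#' In-plane, each output patch contributes its central region (half the
#' overlap discarded per side, except at volume edges). Through-plane,
#' overlapping slab outputs are grouped by slab offset modulo `M` into up to
#' `M` candidate volumes; within a candidate, slabs tile the slice axis
#' exactly. Slices a candidate does not reach are `NA` (boundary slices
#' appear in fewer than `M` candidates).
#'
#' @param outputs List of `list(pos = c(i, j, s), patch = array)` entries
#'   with 0-based low-resolution grid positions and `hr_size x hr_size x N`
#'   output patches.
#' @param target_shape Integer length-3 output volume shape.
#' @param geom A [patch_geometry()].
#' @return List of candidate volumes (each `target_shape`, `NA` where the
#'   candidate has no coverage). Errors if the union of candidates leaves any
#'   voxel uncovered.
#' @export
stitch <- function(outputs, target_shape, geom) {
  stopifnot(inherits(geom, "patch_geometry"), length(outputs) >= 1)
  ts <- as.integer(target_shape)
  lr_dim <- c(ts[1] %/% geom$inplane_scale, ts[2] %/% geom$inplane_scale,
              (ts[3] - geom$N) %/% geom$s_sl + geom$M)  # inferred LR depth
  si <- patch_starts(lr_dim[1], geom$lr_size, geom$lr_overlap) * geom$inplane_scale
  sj <- patch_starts(lr_dim[2], geom$lr_size, geom$lr_overlap) * geom$inplane_scale
  own_i <- own_intervals(si, geom$hr_size, ts[1])
  own_j <- own_intervals(sj, geom$hr_size, ts[2])
  offs <- sort(unique(vapply(outputs, function(o) o$pos[3] %% geom$M, 0)))
  cands <- lapply(offs, function(o) array(NA_real_, ts))
  names(cands) <- as.character(offs)
  for (o in outputs) {
    hi <- o$pos[1] * geom$inplane_scale
    hj <- o$pos[2] * geom$inplane_scale
    hs <- o$pos[3] * geom$s_sl
    ti <- match(hi, si); tj <- match(hj, sj)
    if (is.na(ti) || is.na(tj))
      stop("patch position (", o$pos[1], ",", o$pos[2],
           ") not on the geometry grid", call. = FALSE)
    ri <- (own_i$lo[ti] + 1):own_i$hi[ti]
    rj <- (own_j$lo[tj] + 1):own_j$hi[tj]
    key <- as.character(o$pos[3] %% geom$M)
    cands[[key]][ri, rj, (hs + 1):(hs + geom$N)] <-
      o$patch[ri - hi, rj - hj, , drop = FALSE]
  }
  covered <- Reduce(`|`, lapply(cands, function(c) !is.na(c)))
  if (!all(covered)) {
    bad <- which(!covered, arr.ind = TRUE)
    stop("coverage gap: ", nrow(bad), " voxels uncovered (first at ",
         paste(bad[1, ], collapse = ","), ")", call. = FALSE)
  }
  unname(cands)
}

#' Voxel-wise self-ensemble of candidate reconstructions
#'
#' Unweighted voxel-wise mean over the candidate volumes produced by
#' overlapping slab positions. Voxels missing (`NA`) in some candidates —
#' boundary slices covered by fewer than `M` slabs — average over the
#' candidates that do cover them.
#'
#' @param candidates Nonempty list of equally shaped volumes.
#' @return The averaged volume.
#' @export
self_ensemble <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate volumes", call. = FALSE)
  d <- dim(candidates[[1]])
  for (c in candidates) {
    if (!identical(dim(c), d)) stop("candidate shapes differ", call. = FALSE)
  }
  if (length(candidates) == 1L) {
    out <- candidates[[1]]
    if (anyNA(out)) stop("single candidate has uncovered voxels", call. = FALSE)
    return(out)
  }
  sum_ <- array(0, d); cnt <- array(0, d)
  for (c in candidates) {
    ok <- !is.na(c)
    sum_[ok] <- sum_[ok] + c[ok]
    cnt <- cnt + ok
  }
  if (any(cnt == 0)) stop("voxels uncovered by every candidate", call. = FALSE)
  sum_ / cnt
}
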