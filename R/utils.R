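#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif quantile median sd var pf qf rbinom
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 - 1 and exactly representable as a double.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 69621) %%
    2147483647) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

is_binary_array <- function(x) {
  all(x %in% c(0, 1))
}

# Linear-index offsets of the 26-neighbourhood (or a subset) on a 3D grid.
neighbour_offsets_3d <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), , drop = FALSE]
}

# The 13 unique 3D direction vectors (one per +/- pair), distance 1.
unique_directions_3d <- function() {
  off <- neighbour_offsets_3d()
  keep <- off$dz > 0 |
    (off$dz == 0 & off$dy > 0) |
    (off$dz == 0 & off$dy == 0 & off$dx > 0)
  as.matrix(off[keep, , drop = FALSE])
}

# Shift a 3D logical/numeric array by (dx, dy, dz), zero-filling the border.
shift_array_3d <- function(x, dx, dy, dz, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  src_x <- sx - dx; src_y <- sy - dy; src_z <- sz - dz
  ok_x <- src_x >= 1 & src_x <= d[1]
  ok_y <- src_y >= 1 & src_y <= d[2]
  ok_z <- src_z >= 1 & src_z <= d[3]
  out[sx[ok_x], sy[ok_y], sz[ok_z]] <-
    x[src_x[ok_x], src_y[ok_y], src_z[ok_z]]
  out
}

# Label 26-connected components of a logical 3D array. Returns an integer
# array (0 = background) and the number of components found.
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  idx_all <- which(mask != 0)
  if (length(idx_all) == 0L) {
    return(list(labels = lab, n = 0L))
  }
  inside <- array(FALSE, d)
  inside[idx_all] <- TRUE
  off <- neighbour_offsets_3d()
  # linear offsets are only valid away from the boundary; use coordinate math
  coords <- arrayInd(idx_all, d)
  coord_key <- function(m) (m[, 3] - 1) * (d[1] * d[2]) + (m[, 2] - 1) * d[1] + m[, 1]
  current <- 0L
  unvisited <- array(FALSE, d)
  unvisited[idx_all] <- TRUE
  for (start in idx_all) {
    if (!unvisited[start]) next
    current <- current + 1L
    frontier <- start
    unvisited[start] <- FALSE
    lab[start] <- current
    while (length(frontier) > 0L) {
      fc <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        nb <- cbind(fc[, 1] + off$dx[k], fc[, 2] + off$dy[k], fc[, 3] + off$dz[k])
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        key <- coord_key(nb[ok, , drop = FALSE])
        key <- key[unvisited[key]]
        if (length(key) > 0L) {
          unvisited[key] <- FALSE
          lab[key] <- current
          nxt <- c(nxt, key)
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(labels = lab, n = current)
}

# Quantiles with linear interpolation (R type 7), the convention used for
# all interquartile ranges reported by the package.
q13 <- function(x) unname(quantile(x, c(0.25, 0.75), type = 7))
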