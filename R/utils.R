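# Internal helpers shared across modules.

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_la <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "la4dflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_la("la_parameter_error", "'%s' must be positive and finite", name)
  }
  invisible(x)
}

# World coordinates (mm) of voxel centres along one axis: 0-based index
# times spacing, consistent with a diagonal affine.
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Coordinate arrays for a full grid, each with dim = dims.
grid_coords <- function(dims, spacing_mm) {
  x <- axis_coords(dims[1], spacing_mm[1])
  y <- axis_coords(dims[2], spacing_mm[2])
  z <- axis_coords(dims[3], spacing_mm[3])
  list(
    x = array(rep(x, times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims),
    z = array(rep(z, each = dims[1] * dims[2]), dim = dims)
  )
}

check_same_grid <- function(field, mask) {
  fd <- dim(field$v)
  md <- dim(mask$m)
  if (!identical(fd[c(1, 2, 3)], md[c(1, 2, 3)]) || fd[5] != md[4]) {
    stop_la("la_shape_error",
            "field grid (%s; %d frames) does not match mask grid (%s; %d frames)",
            paste(fd[1:3], collapse = "x"), fd[5],
            paste(md[1:3], collapse = "x"), md[4])
  }
  invisible(TRUE)
}
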