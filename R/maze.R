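# Ground-truth maze world: grid representation, ASCII input/output,
# physics (step/observe), seeded maze synthesis and the breadth-first
# search oracle used throughout the tests.

#' Action vocabulary
#'
#' The fixed, ordered action set. All policy enumeration and every tie-break
#' in the package inherit this order.
#' @export
ACTIONS <- c("up", "down", "left", "right", "stay")

# Row/column displacement per action, in ACTIONS order.
ACTION_DELTAS <- matrix(
  c(-1L, 0L,
    1L, 0L,
    0L, -1L,
    0L, 1L,
    0L, 0L),
  ncol = 2, byrow = TRUE,
  dimnames = list(ACTIONS, c("dr", "dc"))
)

#' Construct a maze grid
#'
#' A maze is a rectangular grid of OPEN/CLOSED cells with a start and a
#' target cell. States are indexed row-major and 1-based:
#' `state = (row - 1) * n_cols + col`, so row 1 is the top of the maze and
#' the conventional "entrance on the lower left" is state
#' `(n_rows - 1) * n_cols + 1`.
#'
#' @param open logical matrix, `TRUE` for OPEN cells.
#' @param start,target 1-based state indices; both must be OPEN.
#' @return an object of class `maze_grid`.
#' @export
maze_grid <- function(open, start, target) {
  if (!is.matrix(open) || !is.logical(open)) {
    stopf("`open` must be a logical matrix")
  }
  n <- length(open)
  for (nm in c("start", "target")) {
    v <- get(nm)
    if (length(v) != 1 || v < 1 || v > n) stopf("invalid %s cell", nm)
  }
  if (!t(open)[start]) stopf("start cell must be OPEN")
  if (!t(open)[target]) stopf("target cell must be OPEN")
  structure(
    list(n_rows = nrow(open), n_cols = ncol(open),
         open = open, start = as.integer(start), target = as.integer(target)),
    class = "maze_grid"
  )
}

#' @export
print.maze_grid <- function(x, ...) {
  cat(sprintf("maze_grid: %d x %d, %d/%d open, start=%d target=%d\n",
              x$n_rows, x$n_cols, sum(x$open), length(x$open),
              x$start, x$target))
  cat(format_maze(x), sep = "\n")
  invisible(x)
}

#' Convert between state index and (row, col)
#'
#' @param maze a `maze_grid` (or any list with `n_cols`).
#' @param state 1-based state index (vectorized).
#' @return `cell_rc`: 2-column integer matrix (row, col);
#'   `cell_index`: integer state index.
#' @export
cell_rc <- function(maze, state) {
  state <- as.integer(state) - 1L
  cbind(row = state %/% maze$n_cols + 1L, col = state %% maze$n_cols + 1L)
}

#' @rdname cell_rc
#' @param row,col 1-based grid coordinates.
#' @export
cell_index <- function(maze, row, col) {
  as.integer((row - 1L) * maze$n_cols + col)
}

is_open <- function(maze, state) {
  rc <- cell_rc(maze, state)
  maze$open[rc]
}

#' Execute one action in the world
#'
#' Physics are total: a move off the boundary (or `stay`) leaves the
#' location unchanged, and CLOSED cells are physically enterable - walls
#' constrain preferences, not movement, which is what makes "mistakes"
#' possible.
#'
#' @param maze a `maze_grid`.
#' @param location current 1-based state index.
#' @param action an element of [ACTIONS] or its index.
#' @return the new 1-based state index.
#' @export
maze_step <- function(maze, location, action) {
  if (is.character(action)) action <- match(action, ACTIONS)
  if (is.na(action) || action < 1 || action > length(ACTIONS)) {
    stopf("unknown action")
  }
  rc <- cell_rc(maze, location)
  r <- rc[1] + ACTION_DELTAS[action, 1]
  c <- rc[2] + ACTION_DELTAS[action, 2]
  if (r < 1 || r > maze$n_rows || c < 1 || c > maze$n_cols) {
    return(as.integer(location))
  }
  cell_index(maze, r, c)
}

#' Observe the current cell
#'
#' Two outcome modalities: `what` reports whether the occupied cell is open
#' (1) or closed (2); `where` is an identity mapping returning the veridical
#' location.
#'
#' @inheritParams maze_step
#' @return list with integer elements `what` (1 = open, 2 = closed) and
#'   `where` (the location).
#' @export
observe_cell <- function(maze, location) {
  list(what = if (is_open(maze, location)) 1L else 2L,
       where = as.integer(location))
}

# ---- ASCII format ----------------------------------------------------------

format_maze <- function(maze) {
  ch <- matrix(ifelse(maze$open, ".", "#"), maze$n_rows, maze$n_cols)
  src <- cell_rc(maze, maze$start); tgt <- cell_rc(maze, maze$target)
  ch[src] <- "S"; ch[tgt] <- "T"
  apply(ch, 1, paste0, collapse = "")
}

#' Read and write the maze ASCII format
#'
#' One line per row; `#` = CLOSED, `.` = OPEN, `S` = start (open),
#' `T` = target (open). The reader/writer round trip is exact.
#'
#' @param path file path (or, for `parse_maze`, a character vector of rows).
#' @return a `maze_grid`.
#' @export
read_maze <- function(path) parse_maze(readLines(path, encoding = "UTF-8"))

#' @rdname read_maze
#' @param lines character vector, one maze row per element.
#' @export
parse_maze <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty maze")
  if (length(unique(nchar(lines))) != 1) stopf("maze must be rectangular")
  ch <- do.call(rbind, strsplit(lines, ""))
  bad <- setdiff(unique(as.vector(ch)), c("#", ".", "S", "T"))
  if (length(bad)) stopf("unknown maze characters: %s", paste(bad, collapse = ""))
  if (sum(ch == "S") != 1 || sum(ch == "T") != 1) {
    stopf("maze needs exactly one S and one T")
  }
  open <- ch != "#"
  dummy <- list(n_cols = ncol(ch))
  srow <- which(ch == "S", arr.ind = TRUE)
  trow <- which(ch == "T", arr.ind = TRUE)
  maze_grid(open,
            cell_index(dummy, srow[1], srow[2]),
            cell_index(dummy, trow[1], trow[2]))
}

#' @rdname read_maze
#' @param maze a `maze_grid`.
#' @export
write_maze <- function(maze, path) {
  writeLines(format_maze(maze), path, useBytes = FALSE)
  invisible(path)
}

# ---- maze synthesis --------------------------------------------------------

#' Generate a random solvable maze
#'
#' Carves a random self-avoiding open path from a bottom-left start to an
#' interior target, then closes each remaining cell independently with
#' probability `wall_density`. Every emitted maze is solvable by
#' construction (the carved path stays open) and deterministic per seed.
#'
#' @param n_rows,n_cols grid dimensions (default 8 x 8).
#' @param wall_density probability in `[0, 1]` that an off-path cell is
#'   CLOSED (default 0.35).
#' @param seed integer seed; the generator uses its own RNG stream and
#'   restores the caller's.
#' @return a `maze_grid`.
#' @export
generate_maze <- function(n_rows = 8, n_cols = 8, wall_density = 0.35,
                          seed = 1) {
  if (n_rows < 2 || n_cols < 2) stopf("maze must be at least 2 x 2")
  if (wall_density < 0 || wall_density > 1) stopf("wall_density must be in [0,1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  dummy <- list(n_cols = n_cols, n_rows = n_rows)
  start <- cell_index(dummy, n_rows, 1L)
  t_r <- sample(seq_len(max(1, floor(n_rows / 2))) + 1L, 1)
  t_c <- sample(seq(max(2, n_cols - 5), n_cols - 1L), 1)
  target <- cell_index(dummy, min(t_r, n_rows - 1L), t_c)

  path <- carve_path(n_rows, n_cols, start, target)
  open <- matrix(stats::runif(n_rows * n_cols) >= wall_density, n_rows, n_cols)
  rc <- cell_rc(dummy, path)
  open[rc] <- TRUE
  m <- maze_grid(open, start, target)
  stopifnot(!is.null(shortest_path(m, start, target)))
  m
}

# Randomized depth-first search producing a self-avoiding path start -> target.
carve_path <- function(n_rows, n_cols, start, target) {
  dummy <- list(n_cols = n_cols, n_rows = n_rows)
  visited <- rep(FALSE, n_rows * n_cols)
  stack <- c(start)
  visited[start] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    if (cur == target) return(stack)
    nb <- grid_neighbours(dummy, cur)
    nb <- nb[!visited[nb]]
    if (!length(nb)) {
      stack <- stack[-length(stack)]
    } else {
      nxt <- if (length(nb) == 1) nb else sample(nb, 1)
      visited[nxt] <- TRUE
      stack <- c(stack, nxt)
    }
  }
  stopf("impossible geometry: no self-avoiding path exists")
}

grid_neighbours <- function(maze, state) {
  rc <- cell_rc(maze, state)
  out <- integer(0)
  for (a in 1:4) {
    r <- rc[1] + ACTION_DELTAS[a, 1]; c <- rc[2] + ACTION_DELTAS[a, 2]
    if (r >= 1 && r <= maze$n_rows && c >= 1 && c <= maze$n_cols) {
      out <- c(out, cell_index(maze, r, c))
    }
  }
  out
}

# ---- breadth-first search oracle ------------------------------------------

#' Shortest open path between two cells
#'
#' Breadth-first search over OPEN, 4-connected cells; neighbour expansion
#' follows the action order so ties resolve deterministically.
#'
#' @param maze a `maze_grid`.
#' @param from,to 1-based state indices.
#' @return integer vector of states from `from` to `to` inclusive (so a
#'   path of `k` moves has length `k + 1`), or `NULL` if disconnected.
#' @export
shortest_path <- function(maze, from = maze$start, to = maze$target) {
  from <- as.integer(from); to <- as.integer(to)
  if (!is_open(maze, from) || !is_open(maze, to)) return(NULL)
  if (from == to) return(from)
  n <- maze$n_rows * maze$n_cols
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (cur in frontier) {
      for (nb in grid_neighbours(maze, cur)) {
        if (!seen[nb] && is_open(maze, nb)) {
          seen[nb] <- TRUE
          prev[nb] <- cur
          if (nb == to) {
            path <- nb
            while (path[1] != from) path <- c(prev[path[1]], path)
            return(path)
          }
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}
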