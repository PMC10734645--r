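# internal helpers shared across modules

.DEG <- 180 / pi

deg2rad <- function(x) x / .DEG
rad2deg <- function(x) x * .DEG

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop(what, " has (near-)zero length and cannot be normalized", call. = FALSE)
  }
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p))) {
    stop("'", name, "' must be a finite numeric 3-vector (mm)", call. = FALSE)
  }
  as.numeric(p)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic child-seed derivation (kept within 32-bit integer range)
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647)
}

# fixed-width numeric formatting used by every serialized table so outputs
# are byte-stable across runs
fmt_num <- function(x, digits = 4L) {
  formatC(x, format = "f", digits = digits)
}

.log_stage <- function(stage, msg) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", msg)
}

write_tsv <- function(df, path, digits = 4L) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], fmt_num, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "trochwarp")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

# session cache for packaged fixtures and derived constants (they are
# read-only, so memoization is safe)
.cache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, force(value), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}
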