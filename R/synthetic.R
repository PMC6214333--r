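#' The built-in 12-node worked example
#'
#' A synthetic coherence network on a 3 x 4 grid (labels `a`..`l`, rows
#' `a b c d` / `e f g h` / `i j k l`) with significance threshold 0.2. The
#' grid's Voronoi adjacency is exactly 4-connectivity. All three FU detection
#' methods have fully known behavior on this network: CCB yields
#' `{a,b,e,f,i,j}` and `{g,d,h,l}`, MCB enumerates the overlapping maximal
#' cliques `{a,b,e,f,g,i,j}` and `{d,g,h,l}` and assigns `g` to the former
#' (total strengths 8.12 vs 4.22), and IWB floods from markers `{a, f, h}` to
#' the same final FUs as MCB.
#'
#' @return A list with `network` (a [coherence_network()]), `layout`, and
#'   `adjacency` (its [voronoi_adjacency()]).
#' @export
table1_network <- function() {
  layout <- fixture_layout("fig3-grid")
  labels <- layout$label
  M <- matrix(0.10, 12L, 12L, dimnames = list(labels, labels))
  set2 <- function(u, v, w) {
    M[u, v] <<- w
    M[v, u] <<- w
  }
  set2("a", "b", 0.65); set2("a", "e", 0.64); set2("a", "f", 0.60)
  set2("a", "g", 0.20); set2("a", "i", 0.30); set2("a", "j", 0.23)
  set2("b", "e", 0.63); set2("b", "f", 0.63); set2("b", "g", 0.21)
  set2("b", "i", 0.32); set2("b", "j", 0.33)
  set2("d", "g", 0.70); set2("d", "h", 0.71); set2("d", "l", 0.70)
  set2("e", "f", 0.62); set2("e", "g", 0.20); set2("e", "i", 0.33)
  set2("e", "j", 0.20)
  set2("f", "g", 0.70); set2("f", "i", 0.30); set2("f", "j", 0.31)
  set2("g", "h", 0.69); set2("g", "i", 0.20); set2("g", "j", 0.20)
  set2("g", "l", 0.70)
  set2("h", "l", 0.72)
  set2("i", "j", 0.32)
  diag(M) <- 0
  network <- coherence_network(layout, M, theta = 0.2)
  list(network = network, layout = layout,
       adjacency = voronoi_adjacency(layout))
}

#' Built-in coherence networks by name
#'
#' @param name currently only `"table1"`, the 12-node worked example.
#' @return As [table1_network()].
#' @export
fixture_network <- function(name = "table1") {
  name <- match.arg(name, "table1")
  table1_network()
}

#' Planted-partition coherence network on a grid
#'
#' Generates a ground-truth benchmark: a `rows x cols` grid layout whose
#' electrodes are partitioned into `n_communities` spatially contiguous
#' patches (seeded round-robin region growing over 4-connectivity, so every
#' truth community is Voronoi-connected), with coherence
#' `within + jitter * U(-1, 1)` inside a community and
#' `between + jitter * U(-1, 1)` across communities, clamped to `[0, 1]`.
#' With `between + jitter < theta < within - jitter`, every community is an
#' isolated spatially connected clique and all three detection methods
#' recover the truth exactly.
#'
#' @param rows,cols grid dimensions.
#' @param n_communities number of planted communities.
#' @param within,between coherence levels (requires `within > between >= 0`).
#' @param jitter half-width of the uniform noise added to each level.
#' @param theta significance threshold attached to the network.
#' @param seed integer seed; the result is reproducible per seed.
#' @return A list with `network`, `layout`, `adjacency`, `truth` (an
#'   [fu_partition()]), and `params`.
#' @export
planted_partition_network <- function(rows, cols, n_communities = 2L,
                                      within = 0.7, between = 0.1,
                                      jitter = 0.05, theta = 0.3,
                                      seed = NULL) {
  if (!(within > between && between >= 0)) stop("need within > between >= 0")
  n <- rows * cols
  if (n_communities > n) {
    stop("cannot grow ", n_communities, " contiguous patches on a ", rows,
         " x ", cols, " grid; use fewer communities")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  layout <- grid_layout(rows, cols)
  labels <- layout$label
  # 4-neighbors on the grid by index
  idx <- matrix(seq_len(n), nrow = rows, ncol = cols, byrow = TRUE)
  nbrs <- lapply(seq_len(n), function(i) {
    r <- (i - 1L) %/% cols + 1L
    k <- (i - 1L) %% cols + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, idx[r - 1L, k])
    if (r < rows) out <- c(out, idx[r + 1L, k])
    if (k > 1L) out <- c(out, idx[r, k - 1L])
    if (k < cols) out <- c(out, idx[r, k + 1L])
    out
  })
  member <- rep(0L, n)
  seeds <- sample(n, n_communities)
  member[seeds] <- seq_len(n_communities)
  remaining <- n - n_communities
  while (remaining > 0L) {
    grew <- FALSE
    for (g in seq_len(n_communities)) {
      frontier <- unique(unlist(nbrs[which(member == g)]))
      frontier <- frontier[member[frontier] == 0L]
      if (length(frontier) == 0L) next
      pickv <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
      member[pickv] <- g
      remaining <- remaining - 1L
      grew <- TRUE
      if (remaining == 0L) break
    }
    if (!grew) stop("region growing stalled; use fewer communities")
  }
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      lev <- if (member[i] == member[j]) within else between
      w <- min(max(lev + jitter * stats::runif(1, -1, 1), 0), 1)
      M[i, j] <- w
      M[j, i] <- w
    }
  }
  truth <- fu_partition(stats::setNames(member, labels))
  network <- coherence_network(layout, M, theta)
  list(network = network, layout = layout,
       adjacency = voronoi_adjacency(layout), truth = truth,
       params = list(rows = rows, cols = cols,
                     n_communities = n_communities, within = within,
                     between = between, jitter = jitter, theta = theta,
                     seed = seed))
}

#' Simulate a segmented multichannel recording with planted coherence
#'
#' Each truth community shares a latent narrowband source — a unit-power
#' sinusoid at `source_freq` with an independent uniform random phase per
#' segment — and every channel records
#' `sqrt(snr) * source + white noise (sd 1)`, so `snr` is the
#' source-to-noise power ratio. Channels in different communities get
#' independent sources (independent phase sequences), so between-community
#' coherence follows the independence null. `snr = Inf` gives the pure
#' source; `snr = 0` gives independent white noise on every channel.
#'
#' @param layout an [electrode_layout()].
#' @param truth an [fu_partition()] over the layout's labels.
#' @param L segments, `T` samples per segment, `fs` sampling rate (Hz).
#' @param T samples per segment.
#' @param fs sampling rate (Hz).
#' @param source_freq source frequency in Hz (should sit on a bin,
#'   i.e. be a multiple of `fs / T`, for maximal band coherence).
#' @param snr source-to-noise power ratio (0, finite, or `Inf`).
#' @param seed integer seed; reproducible per seed.
#' @return A [segmented_recording()].
#' @export
simulate_recording <- function(layout, truth, L = 13L, T = 256L, fs = 256,
                               source_freq = 10, snr = 1, seed = NULL) {
  stopifnot(inherits(layout, "electrode_layout"),
            inherits(truth, "fu_partition"))
  if (L < 2L) stop("L must be at least 2")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  labels <- layout$label
  member <- truth$membership[labels]
  if (anyNA(member)) stop("truth partition does not cover the layout")
  n <- length(labels)
  ncomm <- length(truth$communities)
  tt <- seq(0, T - 1) / fs
  data <- array(0, dim = c(n, L, T))
  for (s in seq_len(L)) {
    phases <- stats::runif(ncomm, 0, 2 * pi)
    src <- vapply(seq_len(ncomm), function(g) {
      sqrt(2) * sin(2 * pi * source_freq * tt + phases[g])
    }, numeric(T))
    for (i in seq_len(n)) {
      noise <- stats::rnorm(T)
      data[i, s, ] <- if (is.infinite(snr)) {
        src[, member[i]]
      } else {
        sqrt(snr) * src[, member[i]] + noise
      }
    }
  }
  segmented_recording(data, labels, fs)
}
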