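# Exact stochastic (Gillespie) simulation under piecewise-constant ATP.

#' Simulate a gating trajectory
#'
#' Runs the exact stochastic simulation algorithm for the continuous-time
#' Markov chain defined by `graph` under a piecewise-constant ATP
#' [protocol()]. At each schedule breakpoint the pending dwell is redrawn
#' under the new generator, which is exact for a memoryless chain. Every
#' firing of the hydrolysis transition (`k3`, `OPEN_pre -> OPEN_post`) is
#' recorded. Identical `(graph, protocol, seed)` give bit-identical paths
#' (R's default Mersenne-Twister stream, one `set.seed(seed)` per call).
#'
#' @param graph A `state_graph`.
#' @param protocol A [protocol()]. Dephosphorylated protocols force
#'   `k1 = 0`.
#' @param seed Integer seed.
#' @param start_state State name or index to start from; defaults to the
#'   first state of the graph.
#' @return A `state_path`: data frame with columns `state`, `entry_s`,
#'   `dwell_s` whose segments tile `[0, duration]`; attributes
#'   `hydrolysis_events` (times), `seed`, `protocol`, `variant`.
#' @export
simulate_ssa <- function(graph, protocol, seed, start_state = 1L) {
  stopifnot(inherits(graph, "state_graph"), inherits(protocol, "protocol"))
  if (protocol$duration_s <= 0) stop("duration must be > 0")
  graph <- .graph_for_protocol(graph, protocol)
  nm <- graph$states$name
  n <- length(nm)
  if (is.character(start_state)) start_state <- match(start_state, nm)
  if (is.na(start_state) || start_state < 1L || start_state > n)
    stop("invalid start state")

  sched <- protocol$atp_schedule
  n_iv <- nrow(sched)
  iv_end <- c(sched$start_s[-1L], protocol$duration_s)
  # per-interval transition tables
  tabs <- lapply(seq_len(n_iv), function(i) {
    Q <- generator_matrix(graph, sched$atp_molar[i])
    out <- -diag(Q)
    jump <- Q
    diag(jump) <- 0
    list(out = out, jump = jump)
  })
  # hydrolysis edge (if present in this topology)
  hyd_from <- match("OPEN_pre", nm)
  hyd_to <- match("OPEN_post", nm)

  set.seed(as.integer(seed))
  cap <- 4096L
  st_v <- integer(cap); en_v <- numeric(cap); dw_v <- numeric(cap)
  k <- 0L
  hyd <- numeric(0)
  st <- as.integer(start_state)
  t <- 0
  iv <- 1L
  seg_start <- 0
  repeat {
    out <- tabs[[iv]]$out[st]
    # time to next event under the current generator (Inf if absorbing)
    d <- if (out <= 0) Inf else stats::rexp(1L, out)
    t_next <- t + d
    if (t_next >= iv_end[iv]) {
      # advance to breakpoint (or end) and redraw memorylessly
      t <- iv_end[iv]
      if (iv == n_iv || t >= protocol$duration_s) {
        k <- k + 1L
        if (k > cap) { cap <- cap * 2L
          st_v <- c(st_v, integer(cap / 2L)); en_v <- c(en_v, numeric(cap / 2L))
          dw_v <- c(dw_v, numeric(cap / 2L)) }
        st_v[k] <- st; en_v[k] <- seg_start; dw_v[k] <- t - seg_start
        break
      }
      iv <- iv + 1L
      next
    }
    # the event fires inside the current interval
    t <- t_next
    nxt <- sample.int(n, 1L, prob = tabs[[iv]]$jump[st, ])
    if (!is.na(hyd_from) && st == hyd_from && nxt == hyd_to)
      hyd <- c(hyd, t)
    k <- k + 1L
    if (k > cap) { cap <- cap * 2L
      st_v <- c(st_v, integer(cap / 2L)); en_v <- c(en_v, numeric(cap / 2L))
      dw_v <- c(dw_v, numeric(cap / 2L)) }
    st_v[k] <- st; en_v[k] <- seg_start; dw_v[k] <- t - seg_start
    st <- nxt
    seg_start <- t
  }
  seg <- data.frame(state = nm[st_v[seq_len(k)]],
                    entry_s = en_v[seq_len(k)],
                    dwell_s = dw_v[seq_len(k)],
                    stringsAsFactors = FALSE)
  # merge zero-length artefacts and adjacent same-state segments
  seg <- seg[seg$dwell_s > 0 | seq_len(nrow(seg)) == 1L, , drop = FALSE]
  if (nrow(seg) > 1L) {
    same <- c(FALSE, seg$state[-1L] == seg$state[-nrow(seg)])
    grp <- cumsum(!same)
    seg <- data.frame(
      state = seg$state[!same],
      entry_s = seg$entry_s[!same],
      dwell_s = as.numeric(tapply(seg$dwell_s, grp, sum)),
      stringsAsFactors = FALSE)
  }
  cls <- graph$states[, intersect(c("name", "fret_class", "pore_conducting"),
                                  names(graph$states)), drop = FALSE]
  structure(seg, class = c("state_path", "data.frame"),
            hydrolysis_events = hyd, seed = as.integer(seed),
            protocol = protocol, variant = graph$variant,
            state_classes = cls)
}

#' Hydrolysis event times of a simulated path
#' @param path A `state_path`.
#' @return Numeric vector of event times in seconds.
#' @export
hydrolysis_events <- function(path) {
  stopifnot(inherits(path, "state_path"))
  attr(path, "hydrolysis_events")
}

#' Time fraction spent per state
#' @param path A `state_path`.
#' @return Named numeric vector of occupancy fractions.
#' @export
state_time_fractions <- function(path) {
  stopifnot(inherits(path, "state_path"))
  tf <- tapply(path$dwell_s, path$state, sum)
  tf / sum(tf)
}

#' Write a simulated path to CSV with a JSON sidecar
#'
#' The CSV holds `state,entry_s,dwell_s`; the sidecar records seed,
#' variant and a hash of the protocol for provenance.
#'
#' @param path A `state_path`.
#' @param file CSV file name; the sidecar gets extension `.json`.
#' @return `file`, invisibly.
#' @export
write_state_path <- function(path, file) {
  stopifnot(inherits(path, "state_path"))
  utils::write.csv(as.data.frame(path)[, c("state", "entry_s", "dwell_s")],
                   file, row.names = FALSE)
  proto <- attr(path, "protocol")
  side <- list(seed = attr(path, "seed"), variant = attr(path, "variant"),
               protocol = list(
                 phosphorylated = proto$phosphorylated,
                 duration_s = proto$duration_s,
                 atp_schedule = proto$atp_schedule),
               protocol_hash = .config_hash(proto),
               n_hydrolysis = length(attr(path, "hydrolysis_events")))
  jsonlite::write_json(side, sub("\\.csv$", ".json", file),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a simulated path written by [write_state_path()]
#' @param file CSV file name.
#' @return A `state_path` (sidecar metadata re-attached when present).
#' @export
read_state_path <- function(file) {
  seg <- utils::read.csv(file, stringsAsFactors = FALSE)
  side_file <- sub("\\.csv$", ".json", file)
  side <- if (file.exists(side_file)) jsonlite::read_json(side_file) else list()
  structure(seg, class = c("state_path", "data.frame"),
            hydrolysis_events = numeric(0),
            seed = side$seed, variant = side$variant)
}

# md5 of the canonical JSON serialization (used for provenance hashes)
.config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(f))
}
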