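# Extended 10-20 montage utilities.
#
# A 64-channel layout (62 scalp sites + A1/A2 ear references) with 3D
# unit-sphere positions constructed from a schematic head grid: each
# scalp site has an anterior-posterior coordinate (row) and a lateral
# coordinate (column) on the unit disk, mapped to the upper hemisphere
# by an azimuthal-equidistant projection. The geometry is schematic but
# preserves what the analysis needs: neighborhood structure and
# left/right/anterior/posterior topography.

scalp_rows <- function() {
  list(Fp = c("Fp1", "Fpz", "Fp2"),
       AF = c("AF7", "AF3", "AFz", "AF4", "AF8"),
       F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
       FC = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
       C  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
       CP = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
       P  = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
       PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
       O  = c("O1", "Oz", "O2"))
}

#' Default channel labels
#'
#' For 64 channels, the packaged extended 10-20 montage (62 scalp sites
#' plus the A1/A2 ear electrodes, with TP9/TP10 near the mastoids); for
#' other counts, a generic \code{Ch01, Ch02, ...} labelling.
#'
#' @param n Number of channels.
#' @return Character vector of length \code{n}.
#' @export
default_channel_labels <- function(n) {
  if (n == 64L) {
    rows <- scalp_rows()
    scalp <- unlist(rows, use.names = FALSE) # 61 grid sites
    # drop AFz to make room: 60 grid + TP9/TP10 = 62 scalp, + A1/A2 = 64
    c(scalp[-which(scalp == "AFz")], "TP9", "TP10", "A1", "A2")
  } else {
    sprintf("Ch%02d", seq_len(n))
  }
}

#' 3D electrode positions for a set of labels
#'
#' Returns unit-sphere positions (x = right, y = anterior, z = up) for
#' the packaged schematic extended 10-20 layout. Unknown labels are
#' placed on a circle below the equator so distance-based adjacency
#' still works; generic \code{ChNN} labels get an evenly spaced grid.
#'
#' @param labels Character vector of channel labels.
#' @return \code{length(labels) x 3} matrix with rownames = labels.
#' @export
montage_positions <- function(labels) {
  rows <- scalp_rows()
  u_row <- c(Fp = 0.8, AF = 0.6, F = 0.4, FC = 0.2, C = 0,
             CP = -0.2, P = -0.4, PO = -0.6, O = -0.8)
  tab <- list()
  for (rn in names(rows)) {
    labs <- rows[[rn]]
    k <- length(labs)
    # lateral coordinates symmetric about the midline, rim at |v| = 0.8
    v <- seq(-0.8, 0.8, length.out = k)
    for (i in seq_len(k)) tab[[labs[i]]] <- c(v = v[i], u = u_row[[rn]])
  }
  tab[["TP9"]]  <- c(v = -1.0, u = -0.2)
  tab[["TP10"]] <- c(v = 1.0, u = -0.2)
  tab[["A1"]]   <- c(v = -1.1, u = 0)
  tab[["A2"]]   <- c(v = 1.1, u = 0)

  disk_to_sphere <- function(v, u) {
    r <- sqrt(v^2 + u^2)
    theta <- min(r, 1.15) * (pi / 2) # polar angle from vertex; ears dip below equator
    if (r == 0) return(c(0, 0, 1))
    c(sin(theta) * v / r, sin(theta) * u / r, cos(theta))
  }

  n <- length(labels)
  pos <- matrix(NA_real_, nrow = n, ncol = 3,
                dimnames = list(labels, c("x", "y", "z")))
  generic <- grepl("^Ch[0-9]+$", labels)
  if (any(generic)) {
    # evenly spaced spiral over the upper hemisphere
    k <- sum(generic)
    idx <- seq_len(k)
    th <- acos(1 - idx / (k + 1))
    ph <- idx * pi * (3 - sqrt(5))
    pos[generic, ] <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  for (i in which(!generic)) {
    lb <- labels[i]
    if (!is.null(tab[[lb]])) {
      pos[i, ] <- disk_to_sphere(tab[[lb]][["v"]], tab[[lb]][["u"]])
    } else {
      # unknown named channel: park below the equator, spread by hash
      h <- sum(utf8ToInt(lb))
      pos[i, ] <- c(cos(h), sin(h), -0.5) / sqrt(1.25)
    }
  }
  pos
}

#' Distance-based channel adjacency
#'
#' Two channels are neighbors when their Euclidean distance is at most
#' \code{prop} times the maximum inter-electrode distance of the
#' montage. On the packaged 64-channel layout the default yields a
#' connected graph with a handful of neighbors per channel.
#'
#' @param positions channels x 3 position matrix.
#' @param prop Fraction of the maximum inter-electrode distance.
#' @return Logical adjacency matrix (no self-adjacency).
#' @export
channel_adjacency <- function(positions, prop = 0.4) {
  D <- as.matrix(dist(positions))
  thr <- prop * max(D)
  A <- D > 0 & D <= thr
  dimnames(A) <- dimnames(D)
  A
}

# Connected components of a channel subset under an adjacency matrix.
# Returns a list of integer vectors (indices into `members`).
connected_components <- function(members, adj) {
  if (length(members) == 0L) return(list())
  seen <- rep(FALSE, length(members))
  comps <- list()
  sub <- adj[members, members, drop = FALSE]
  for (s in seq_along(members)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(sub[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- members[comp]
  }
  comps
}
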