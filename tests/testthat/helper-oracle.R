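# Independent reference implementations: plain double loops over pixel
# positions / gray-level pairs, no vectorization, no shared code with the
# package. Used as oracles for the fast implementations.

refGLCM <- function(px, ng, dx, dy, cyclic = FALSE, symmetric = FALSE) {
  ny <- nrow(px); nx <- ncol(px)
  counts <- matrix(0, ng, ng)
  for (y in 0:(ny - 1L)) {
    for (x in 0:(nx - 1L)) {
      tx <- x + dx; ty <- y + dy
      if (cyclic) {
        tx <- tx %% nx; ty <- ty %% ny
      } else if (tx < 0 || tx >= nx || ty < 0 || ty >= ny) {
        next
      }
      i <- px[y + 1L, x + 1L]; j <- px[ty + 1L, tx + 1L]
      counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

refASM <- function(p) {
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    s <- s + p[i, j]^2
  s
}

refContrast <- function(p) {
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    s <- s + (i - j)^2 * p[i, j]
  s
}

refCorrelation <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  lev <- 0:(ng - 1L)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum(lev^2 * px) - mx^2)
  sy <- sqrt(sum(lev^2 * py) - my^2)
  if (sx == 0 || sy == 0) return(NaN)
  s <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng))
    s <- s + (i - 1) * (j - 1) * p[i, j]
  (s - mx * my) / (sx * sy)
}

refIDM <- function(p, squared = FALSE) {
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    w <- if (squared) 1 / (1 + (i - j)^2) else 1 / (1 + abs(i - j))
    s <- s + p[i, j] * w
  }
  s
}

randomGrayMatrix <- function(nx, ny, ng) {
  matrix(sample(0:(ng - 1L), nx * ny, replace = TRUE), nrow = ny)
}

randomProbMatrix <- function(ng) {
  m <- matrix(stats::rexp(ng * ng), ng, ng)
  m / sum(m)
}

# sawtooth GLCM fixture: cyclic unit-width image, height = whole periods
gradientGLCM <- function(ng, nabla, d, periods = 1L, width = 2L) {
  nt <- effectiveLevels(ng, nabla)
  img <- makeLinearGradient(GradientSpec(nLevels = ng, nabla = nabla,
                                         width = width,
                                         height = nt * periods))
  computeGLCM(img, 0L, d, cyclic = TRUE)
}
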