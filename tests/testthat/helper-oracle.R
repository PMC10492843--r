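# Frozen reference values from an independent arbitrary-precision Lorenz-Mie
# series implementation (50-digit arithmetic; Riccati-Bessel functions
# evaluated directly from spherical Bessel functions, adaptive truncation).

# m = 1.42/1.35, tissue scatterer in tissue medium
mie_oracle_tissue <- list(
  list(x = 0.1, Qsca = 3.1172904084201865e-7, g = 0.0016320071683024467,
       S = list(
         `1` = list(S1 = complex(real = 7.7932260210504662e-10, imaginary = -3.4259794874202421e-5),
                    S2 = complex(real = 7.7932260210504662e-10, imaginary = -3.4259794874202421e-5)),
         `0.5` = list(S1 = complex(real = 7.7932195319093048e-10, imaginary = -3.4225063972319815e-5),
                      S2 = complex(real = 3.8966125759405418e-10, imaginary = -1.7113617925318699e-5)),
         `0` = list(S1 = complex(real = 7.7932130427695792e-10, imaginary = -3.4190358020908543e-5),
                    S2 = complex(real = 3.746647309182593e-16, imaginary = -1.4471827136110141e-9)),
         `-1` = list(S1 = complex(real = 7.7932000644944355e-10, imaginary = -3.4121020913886057e-5),
                     S2 = complex(real = -7.7932000644944355e-10, imaginary = 3.4121020913886057e-5)))),
  list(x = 1, Qsca = 0.0022128544239944463, g = 0.16894842638643711,
       S = list(
         `1` = list(S1 = complex(real = 0.00055321360599861157, imaginary = -0.034895019350349686),
                    S2 = complex(real = 0.00055321360599861157, imaginary = -0.034895019350349686)),
         `0.5` = list(S1 = complex(real = 0.00054820478543816298, imaginary = -0.031508500320706697),
                      S2 = complex(real = 0.00027630136159508301, imaginary = -0.015866772506854653)),
         `0` = list(S1 = complex(real = 0.00054320760032028562, imaginary = -0.028359196199975709),
                    S2 = complex(real = 2.9275322260404757e-6, imaginary = -0.00014291308056045994)),
         `-1` = list(S1 = complex(real = 0.00053324809207139237, imaginary = -0.022720702767959717),
                     S2 = complex(real = -0.00053324809207139237, imaginary = 0.022720702767959717)))),
  list(x = 5, Qsca = 0.12724583850542079, g = 0.90822053488118367,
       S = list(
         `1` = list(S1 = complex(real = 0.79528649065887995, imaginary = -4.3842731092567303),
                    S2 = complex(real = 0.79528649065887995, imaginary = -4.3842731092567303)),
         `0.5` = list(S1 = complex(real = -0.018760396547064342, imaginary = 0.32188598338392747),
                      S2 = complex(real = 0.027856974431745989, imaginary = 0.17322514453749726)),
         `0` = list(S1 = complex(real = -0.055609167652400536, imaginary = 0.096123132313588875),
                    S2 = complex(real = -0.031711093480108206, imaginary = 0.013474613303280486)),
         `-1` = list(S1 = complex(real = 0.031213560210613272, imaginary = -0.025150831938234279),
                     S2 = complex(real = -0.031213560210613272, imaginary = 0.025150831938234279)))),
  list(x = 20, Qsca = 1.7630041358391339, g = 0.98830357531748482,
       S = list(
         `1` = list(S1 = complex(real = 176.30041358391339, imaginary = -182.88599618835471),
                    S2 = complex(real = 176.30041358391339, imaginary = -182.88599618835471)),
         `0.5` = list(S1 = complex(real = 0.14415971915763505, imaginary = -1.0206923277955601),
                      S2 = complex(real = -0.27150989075377699, imaginary = -0.79971573470949628)),
         `0` = list(S1 = complex(real = 0.33532842520145899, imaginary = 0.4006134484581298),
                    S2 = complex(real = 0.1449093747034036, imaginary = 0.31866720160279205)),
         `-1` = list(S1 = complex(real = -0.00012435099806932273, imaginary = 0.002612806733140329),
                     S2 = complex(real = 0.00012435099806932273, imaginary = -0.002612806733140329)))))

# m = 1.05 cases (low-contrast spheres)
mie_oracle_m105 <- list(
  list(x = 5, Qsca = 0.11821678876280353, g = 0.90825413616391509,
       S = list(
         `0.8` = list(S1 = complex(real = 0.29868765231040717, imaginary = -1.1600524793635637),
                      S2 = complex(real = 0.30061483567682687, imaginary = -0.95904904814112176)),
         `0` = list(S1 = complex(real = -0.052302222430045761, imaginary = 0.095225853515895655),
                    S2 = complex(real = -0.029166110173437172, imaginary = 0.012891572133515262)),
         `-0.6` = list(S1 = complex(real = 0.067782875230049258, imaginary = -0.16621488799793915),
                       S2 = complex(real = -0.034927563775277894, imaginary = 0.079391333315888481)))),
  list(x = 3, Qsca = 0.038110374225362919, g = 0.79145561340369768,
       S = list(
         `0.8` = list(S1 = complex(real = 0.067815301640202667, imaginary = -0.62213389135670512),
                      S2 = complex(real = 0.06128790241048225, imaginary = -0.50700572819386731),
                      m11 = 0.32623025465722934, m12 = -0.065419239253958897,
                      m33 = 0.31958170421025276, m34 = -0.0037465348289455929),
         `0` = list(S1 = complex(real = 0.012810130154887324, imaginary = -0.018120799947651874),
                    S2 = complex(real = 0.013378411479104142, imaginary = -0.0059502720503605349),
                    m11 = 0.00035342522825275045, m12 = -0.00013903759707522321,
                    m33 = 0.00027920288177165028, m34 = -0.00016620375860810885),
         `-0.6` = list(S1 = complex(real = -0.012660472794567756, imaginary = 0.084488491778751057),
                       S2 = complex(real = 0.013500673440433206, imaginary = -0.049114869965765744),
                       m11 = 0.0049465657247646859, m12 = -0.0023520270896653893,
                       m33 = -0.0043205661961179744, m34 = 0.00051883406196933349))))

# radius (um) giving size parameter x at wavelength lambda (nm), medium 1.35
radius_for_x <- function(x, lambda = 550, n_medium = 1.35) {
  x * (lambda * 1e-3) / (2 * pi * n_medium)
}

# synthetic RGB test frame: smooth pattern times a radial vignette
make_vignette_frame <- function(n = 96, ratio = 3) {
  row <- matrix(seq_len(n), n, n)
  col <- t(row)
  r2 <- (row - (n + 1) / 2)^2 + (col - (n + 1) / 2)^2
  vig <- 1 / (1 + (ratio - 1) * r2 / max(r2))
  pat <- 0.3 + 0.1 * sin(row / 4) * cos(col / 5)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- pat * vig * c(1, 0.9, 0.8)[ch]
  img
}

# synthetic glare fixture: bright-in-co dark-in-cross disc on a textured field
make_glare_pair <- function(n = 256, radius = 10, seed = 1) {
  set.seed(seed)
  row <- matrix(seq_len(n), n, n)
  col <- t(row)
  disc <- (row - n / 2)^2 + (col - n / 2 - 12)^2 <= radius^2
  co <- array(500, c(n, n, 3))
  cross <- array(300, c(n, n, 3))
  for (ch in 1:3) {
    p <- co[, , ch]; p[disc] <- 4095; co[, , ch] <- p
    p <- cross[, , ch]; p[disc] <- 5; cross[, , ch] <- p
  }
  co <- co + array(stats::runif(n * n * 3, 0, 20), c(n, n, 3))
  cross <- cross + array(stats::runif(n * n * 3, 0, 20), c(n, n, 3))
  list(pair = polarized_frame_pair(co, cross), disc = disc)
}

# oriented stripe pattern with a given fiber-axis angle (radians)
make_stripes <- function(n = 256, theta = pi / 6, period = 16) {
  row <- matrix(seq_len(n), n, n)
  col <- t(row)
  sin(2 * pi * (cos(theta + pi / 2) * col + sin(theta + pi / 2) * row) /
        period)^2
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, sum hypergeometric probabilities <= that of the observed table
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  p_of <- function(a) stats::dhyper(a, r1, r2, c1)
  p_obs <- p_of(tab[1, 1])
  sum(vapply(a_min:a_max, function(a) {
    p <- p_of(a)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}
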