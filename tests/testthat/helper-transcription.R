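# Independently re-typed coefficient table of the twenty published
# piecewise-linear membership functions (second transcription, used to
# cross-check the one inside default_knowledge_base()).
retyped_coefficients <- function() {
  read.csv(text = "factor,term,lower,upper,slope,intercept
X1,L,1.83,2.06,-2.17,4.97
X1,L,2.06,2.76,-0.71,1.97
X1,LA,1.83,2.06,2.17,-3.48
X1,LA,2.06,2.3,-2.08,5.29
X1,LA,2.3,2.76,-1.09,3.0
X1,A,1.83,2.3,2.13,-3.89
X1,A,2.3,2.76,-2.17,6
X1,HA,1.83,2.3,1.06,-1.94
X1,HA,2.3,2.53,2.17,-4.5
X1,HA,2.53,2.76,-2.17,6.5
X1,H,1.83,2.53,0.71,-1.31
X1,H,2.53,2.76,2.17,-5
X2,L,1.74,2.06,-1.56,3.72
X2,L,2.06,3.0,-0.53,1.6
X2,LA,1.74,2.06,1.56,-2.22
X2,LA,2.06,2.37,-1.61,4.3
X2,LA,2.37,3.0,-0.79,2.38
X2,A,1.74,2.3,1.59,-2.76
X2,A,2.3,3.0,-1.59,4.76
X2,HA,1.74,2.37,0.79,-1.38
X2,HA,2.37,2.69,1.56,-3.2
X2,HA,2.69,3.0,-1.61,5.34
X2,H,1.74,2.53,0.53,-0.92
X2,H,2.53,3.0,1.61,-3.84
X3,L,1.0,1.34,-1.47,2.47
X3,L,1.34,2.35,-0.495,1.16
X3,LA,1.0,1.34,1.47,-0.97
X3,LA,1.34,1.68,-1.47,2.97
X3,LA,1.68,2.35,-0.74,1.75
X3,A,1.0,1.68,1.47,-1.47
X3,A,1.68,2.35,-1.49,3.5
X3,HA,1.0,1.68,0.73,-0.73
X3,HA,1.68,2.02,1.47,-1.97
X3,HA,2.02,2.35,-1.52,4.06
X3,H,1.0,2.02,0.49,-0.49
X3,H,2.02,2.35,1.52,-2.56
X4,L,2.07,2.72,-0.769,2.59
X4,L,2.72,4.67,-0.26,1.197
X4,LA,2.07,2.72,0.769,-1.09
X4,LA,2.72,3.37,-0.769,3.09
X4,LA,3.37,4.67,-0.38,1.796
X4,A,2.07,3.37,0.769,-1.59
X4,A,3.37,4.67,-0.769,3.59
X4,HA,2.07,3.37,0.38,-0.796
X4,HA,3.37,4.02,0.769,-2.09
X4,HA,4.02,4.67,-0.769,4.09
X4,H,2.07,4.02,0.25,-0.53
X4,H,4.02,4.67,0.769,-2.59
", stringsAsFactors = FALSE)
}

# uniform in-domain patient draws, given the current RNG state
random_patients <- function(n, kb) {
  doms <- lapply(kb$variables, `[[`, "domain")
  out <- lapply(doms, function(d) runif(n, d[1], d[2]))
  names(out) <- tolower(names(doms))
  as.data.frame(out)
}

uap_fixture <- c(x1 = 2.15, x2 = 2.50, x3 = 1.00, x4 = 2.50)

# hand evaluation of the worked example, written out as arithmetic on the
# printed coefficients (independent of the engine)
uap_expected_memberships <- function() {
  cl <- function(v) min(1, max(0, v))
  # fuzzified degrees at (2.15, 2.50, 1.00, 2.50)
  d <- list(
    X1 = c(L = cl(1.97 - 0.71 * 2.15), LA = cl(5.29 - 2.08 * 2.15),
           A = cl(2.13 * 2.15 - 3.89), HA = cl(1.06 * 2.15 - 1.94),
           H = cl(0.71 * 2.15 - 1.31)),
    X2 = c(L = cl(1.6 - 0.53 * 2.5), LA = cl(2.38 - 0.79 * 2.5),
           A = cl(4.76 - 1.59 * 2.5), HA = cl(1.56 * 2.5 - 3.2),
           H = cl(0.53 * 2.5 - 0.92)),
    X3 = c(L = cl(2.47 - 1.47 * 1), LA = cl(1.47 * 1 - 0.97),
           A = cl(1.47 * 1 - 1.47), HA = cl(0.73 * 1 - 0.73),
           H = cl(0.49 * 1 - 0.49)),
    X4 = c(L = cl(2.59 - 0.769 * 2.5), LA = cl(0.769 * 2.5 - 1.09),
           A = cl(0.769 * 2.5 - 1.59), HA = cl(0.38 * 2.5 - 0.796),
           H = cl(0.25 * 2.5 - 0.53)))
  r <- function(t1, t2, t3, t4) {
    min(d$X1[[t1]], d$X2[[t2]], d$X3[[t3]], d$X4[[t4]])
  }
  c(I = max(r("HA", "A", "L", "A"), r("HA", "HA", "L", "A"),
            r("HA", "HA", "L", "HA")),
    II = max(r("LA", "A", "L", "H"), r("A", "HA", "L", "LA"),
             r("LA", "HA", "L", "LA"), r("A", "L", "L", "LA")),
    III = max(r("HA", "LA", "HA", "HA"), r("HA", "LA", "HA", "H"),
              r("L", "A", "HA", "H")),
    IV = max(r("L", "L", "A", "A"), r("LA", "L", "A", "A"),
             r("L", "LA", "LA", "LA"), r("LA", "LA", "LA", "LA")))
}
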