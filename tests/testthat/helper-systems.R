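# Fixture builders shared across the suite. Everything is generated in code.

# a straight root between two points with constant diameter
straightRoot <- function(id, from, to, d, n = 2, order = 1L,
                         parentId = NA_character_, insertion = NA_real_) {
  t <- seq(0, 1, length.out = n)
  Root(id, cbind(x = from[1] + t * (to[1] - from[1]),
                 y = from[2] + t * (to[2] - from[2]),
                 diameter = rep(d, n)),
       order = order, parentId = parentId, insertion = insertion)
}

# main axis (5,0)->(5,10) d = 0.1 with one lateral inserted at arc 5,
# length 5, d = 0.05: surface pi*(0.1*10) + pi*(0.05*5) = 1.25*pi
toySystem <- function() {
  RootSystem(list(
    straightRoot("main", c(5, 0), c(5, 10), 0.1),
    straightRoot("lat", c(5, 5), c(10, 5), 0.05, order = 2L,
                 parentId = "main", insertion = 5)
  ), label = "toy", extent = c(20, 20))
}

# compact generator settings for oracle sweeps: a 20 x 20 cm frame and
# sparser branching keep brute-force comparisons fast
smallParams <- function() {
  architectureParams(extent = c(20, 20),
                     lateralDensity = c(0.4, 0.15),
                     lateralLengthRange = list(c(1, 5), c(0.3, 1.5)))
}
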