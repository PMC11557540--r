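# Shared fixtures, built in code.

# one unit tetrahedron (volume 1/6)
unitTet <- function() {
  tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          matrix(1:4, 1))
}

# two tets sharing a face; volumes 1/6 and 1/2 (second is scaled in z)
twoTets <- function() {
  tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, -3)),
          rbind(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 5L)))
}

# a small but non-trivial patient (fast enough for per-test forward runs)
smallPatient <- function(seed = 3, ...) {
  makeSyntheticPatient(seed = seed, semiAxes = c(14, 12, 13), elementSize = 5,
                       tumourRadius = 5.5, pt = 0.03, psaNoiseSD = 0, ...)
}

tableCaps <- carryingCapacities()
tableGrowth <- growthParams()
tableOxygen <- oxygenParams()
tableMech <- mechanicsParams()
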