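# Resolved channel manifest for the nano-scale model variants.
# RGCSPELAN entries are (stem width c, branch width m) per replacement site,
# in layer order; LSCD entries are the per-level unify width and the two
# shared trunk widths. Calibrated so whole-model parameter totals and the
# deploy-mode FLOP ratio reproduce the published accounting exactly.
rgcspelan_only:
  sites:
    - {layer: 3,  c1: 32,  c2: 32,  n: 1, c: 16,  m: 8}
    - {layer: 5,  c1: 64,  c2: 64,  n: 2, c: 32,  m: 16}
    - {layer: 7,  c1: 128, c2: 128, n: 2, c: 49,  m: 49}
    - {layer: 9,  c1: 256, c2: 256, n: 1, c: 128, m: 64}
    - {layer: 13, c1: 384, c2: 128, n: 1, c: 64,  m: 32}
    - {layer: 16, c1: 192, c2: 64,  n: 1, c: 32,  m: 16}
    - {layer: 19, c1: 192, c2: 128, n: 1, c: 64,  m: 32}
    - {layer: 22, c1: 384, c2: 256, n: 1, c: 128, m: 64}
yolov8_rl:
  sites:
    - {layer: 3,  c1: 32,  c2: 32,  n: 1, c: 16,  m: 8}
    - {layer: 5,  c1: 64,  c2: 64,  n: 2, c: 32,  m: 16}
    - {layer: 7,  c1: 128, c2: 128, n: 2, c: 49,  m: 64}
    - {layer: 9,  c1: 256, c2: 256, n: 1, c: 128, m: 64}
    - {layer: 13, c1: 384, c2: 128, n: 1, c: 64,  m: 51}
    - {layer: 16, c1: 192, c2: 64,  n: 1, c: 32,  m: 16}
    - {layer: 19, c1: 192, c2: 128, n: 1, c: 64,  m: 67}
    - {layer: 22, c1: 384, c2: 256, n: 1, c: 126, m: 78}
lscd:
  h: 65
  t1: 55
  t2: 64
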