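# Default vein phantom: tissue disk (T2* 48 ms) with two fast-decaying
# vein-like lines and a slow-decaying nodule over an air background,
# Rician magnitude noise, on the 12-echo schedule TE = 2.61 + 3.3k ms.
# Matches vein_phantom_spec().
shape: [96, 96]
seed: 20260923
noise:
  model: rician
  sigma: 1.0
regions:
  - type: disk
    center: [48.5, 48.5]
    radius: 40.32
    w: 100
    t2star_ms: 48
  - type: line
    from: [24.5, 21.62]
    to: [69.62, 58.1]
    thickness: 2.88
    w: 110
    t2star_ms: 12
  - type: line
    from: [67.7, 34.1]
    to: [43.7, 77.3]
    thickness: 2
    w: 110
    t2star_ms: 12
  - type: disk
    center: [31.22, 65.78]
    radius: 5.76
    w: 80
    t2star_ms: 70
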