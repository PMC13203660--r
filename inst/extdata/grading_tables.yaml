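# Expert suitability grading rules, one entry per environmental variable.
# Interval conditions are unions of half-open [low, high) intervals; .inf
# denotes an open upper bound. Values matched by no rule fall back to the
# least-suitable score 1. Land-cover codes: 1 other, 2 desert, 3 forest,
# 4 gravels, 5 farmland, 6 grassland, 7 meadow. Aspect codes: 0 flat, 1 N,
# 2 NE, 3 E, 4 SE, 5 S, 6 SW, 7 W, 8 NW.
variables:
  - name: temp_dev
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[0, 4], [30, .inf]]
      - score: 2
        intervals: [[4, 8], [28, 30]]
      - score: 3
        intervals: [[8, 12], [25, 28]]
      - score: 4
        intervals: [[12, 16], [22, 25]]
      - score: 5
        intervals: [[16, 22]]
  - name: precip_dev
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[0, 100], [800, .inf]]
      - score: 2
        intervals: [[100, 160], [650, 800]]
      - score: 3
        intervals: [[160, 220], [520, 650]]
      - score: 4
        intervals: [[220, 280], [420, 520]]
      - score: 5
        intervals: [[280, 420]]
  - name: lst_winter
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[-.inf, -20]]
      - score: 2
        intervals: [[-20, -10]]
      - score: 3
        intervals: [[-10, -5]]
      - score: 4
        intervals: [[-5, 0]]
      - score: 5
        intervals: [[0, .inf]]
  - name: precip_winter
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[0, 50], [200, .inf]]
      - score: 2
        intervals: [[150, 200]]
      - score: 3
        intervals: [[50, 90]]
      - score: 4
        intervals: [[120, 150]]
      - score: 5
        intervals: [[90, 120]]
  - name: ndvi_dev
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[0, 0.10], [0.65, .inf]]
      - score: 3
        intervals: [[0.10, 0.15], [0.55, 0.65]]
      - score: 4
        intervals: [[0.15, 0.25], [0.45, 0.55]]
      - score: 5
        intervals: [[0.25, 0.45]]
  - name: land_cover
    kind: categorical
    fallback: 1
    rules:
      - score: 1
        codes: [1]
      - score: 2
        codes: [2, 3]
      - score: 3
        codes: [4]
      - score: 4
        codes: [5]
      - score: 5
        codes: [6, 7]
  - name: aspect
    kind: categorical
    fallback: 1
    rules:
      - score: 1
        codes: [1]
      - score: 2
        codes: [2, 8]
      - score: 3
        codes: [0]
      - score: 4
        codes: [3, 7]
      - score: 5
        codes: [4, 5, 6]
  - name: slope
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[15, .inf]]
      - score: 2
        intervals: [[12, 15]]
      - score: 3
        intervals: [[8, 12]]
      - score: 4
        intervals: [[4, 8]]
      - score: 5
        intervals: [[0, 4]]
  - name: clay
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[0, 80], [480, .inf]]
      - score: 2
        intervals: [[80, 120], [400, 480]]
      - score: 3
        intervals: [[120, 160], [320, 400]]
      - score: 4
        intervals: [[160, 200], [260, 320]]
      - score: 5
        intervals: [[200, 260]]
  - name: sand
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[0, 100], [650, .inf]]
      - score: 2
        intervals: [[100, 160], [550, 650]]
      - score: 3
        intervals: [[160, 220], [450, 550]]
      - score: 4
        intervals: [[220, 280], [360, 450]]
      - score: 5
        intervals: [[280, 360]]
  - name: dist_river
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[2.5, .inf]]
      - score: 2
        intervals: [[2.0, 2.5]]
      - score: 3
        intervals: [[1.0, 2.0]]
      - score: 4
        intervals: [[0.4, 1.0]]
      - score: 5
        intervals: [[0, 0.4]]
  - name: dist_lake
    kind: interval
    fallback: 1
    rules:
      - score: 1
        intervals: [[3.0, .inf]]
      - score: 2
        intervals: [[2.2, 3.0]]
      - score: 3
        intervals: [[1.4, 2.2]]
      - score: 4
        intervals: [[0.8, 1.4]]
      - score: 5
        intervals: [[0, 0.8]]
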