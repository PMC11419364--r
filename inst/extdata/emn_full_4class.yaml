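name: emn_full
nClasses: 4
heads:
  '1':
    layer: 15
    stride: 16
    anchors:
    - - 30.0
      - 61.0
    - - 62.0
      - 45.0
    - - 59.0
      - 119.0
  '2':
    layer: 19
    stride: 8
    anchors:
    - - 10.0
      - 13.0
    - - 16.0
      - 30.0
    - - 33.0
      - 23.0
  '3':
    layer: 22
    stride: 16
    anchors:
    - - 45.0
      - 91.0
    - - 93.0
      - 67.0
    - - 88.0
      - 178.0
  '4':
    layer: 25
    stride: 32
    anchors:
    - - 116.0
      - 90.0
    - - 156.0
      - 198.0
    - - 373.0
      - 326.0
layers:
- index: 0
  from: -1.0
  kind: conv
  hyper:
    cout: 16
    k: 3
    stride: 2
    act: hswish
- index: 1
  from: -1.0
  kind: bneck
  hyper:
    kernel: 3
    exp: 16
    cout: 16
    se: yes
    act: relu
    stride: 2
- index: 2
  from: -1.0
  kind: bneck
  hyper:
    kernel: 3
    exp: 72
    cout: 24
    se: no
    act: relu
    stride: 2
- index: 3
  from: -1.0
  kind: bneck
  hyper:
    kernel: 3
    exp: 88
    cout: 24
    se: no
    act: relu
    stride: 1
- index: 4
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 96
    cout: 40
    se: yes
    act: hswish
    stride: 2
- index: 5
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 240
    cout: 40
    se: yes
    act: hswish
    stride: 1
- index: 6
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 240
    cout: 40
    se: yes
    act: hswish
    stride: 1
- index: 7
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 120
    cout: 48
    se: yes
    act: hswish
    stride: 1
- index: 8
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 144
    cout: 48
    se: yes
    act: hswish
    stride: 1
- index: 9
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 288
    cout: 96
    se: yes
    act: hswish
    stride: 2
- index: 10
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 504
    cout: 96
    se: yes
    act: hswish
    stride: 1
- index: 11
  from: -1.0
  kind: bneck
  hyper:
    kernel: 5
    exp: 504
    cout: 96
    se: yes
    act: hswish
    stride: 1
- index: 12
  from: -1.0
  kind: sppf
  hyper:
    hidden: 48
    cout: 96
    k: 5
- index: 13
  from: -1.0
  kind: conv
  hyper:
    cout: 24
    k: 1
    stride: 1
    act: hswish
- index: 14
  from: -1.0
  kind: upsample
- index: 15
  from:
  - 14.0
  - 8.0
  kind: concat
- index: 16
  from: -1.0
  kind: conv
  hyper:
    cout: 136
    k: 1
    stride: 1
    act: hswish
- index: 17
  from: -1.0
  kind: upsample
- index: 18
  from: -1.0
  kind: conv
  hyper:
    cout: 56
    k: 1
    stride: 1
    act: hswish
- index: 19
  from:
  - 18.0
  - 3.0
  kind: concat
- index: 20
  from: -1.0
  kind: conv
  hyper:
    cout: 96
    k: 3
    stride: 2
    act: hswish
- index: 21
  from: -1.0
  kind: conv
  hyper:
    cout: 312
    k: 1
    stride: 1
    act: hswish
- index: 22
  from:
  - 21.0
  - 16.0
  kind: concat
- index: 23
  from: -1.0
  kind: conv
  hyper:
    cout: 80
    k: 3
    stride: 2
    act: hswish
- index: 24
  from: -1.0
  kind: conv
  hyper:
    cout: 336
    k: 1
    stride: 1
    act: hswish
- index: 25
  from:
  - 24.0
  - 13.0
  kind: concat

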