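
Last position-specific scoring matrix computed
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 C  -3   4  -2  -3   4   2   3   1   3   2   3  -4   1  -4   2   0  -1   0  -2  -3
    2 E  -1   2  -2  -3  -3   0   3   0  -3   1  -2   1  -3  -1   0   4   0   0   1   1
    3 S   3   4   2   1  -4   1   3  -1   4   0   4  -1  -4   2  -3  -1  -3   1   0   2
    4 D   3   4  -1   3   4   0   1   0   3   1   0  -1  -4   1   3  -2   4   2  -2   3
    5 E   2   1  -4   4   0   1  -2   3  -4   4  -4  -2  -3  -4  -2   4  -3  -2  -1   0
    6 G   2   2   1   0  -1   0  -3  -4  -3  -3   0   0  -1   0   2   1   3   4   1  -4
    7 H   2   2   0   2   2  -4   2   2   3  -4  -4  -3   0   0   3  -2  -3   0   3  -1
    8 I  -3   0   0   1   3  -4   1  -1  -2   2  -4  -4   0   3   4  -4  -4  -1   1  -4
    9 N  -3   2   1  -2  -1   0  -4   1   2   3   4  -2   0  -3   2  -2  -1   4   0  -1
   10 D   4   3  -3  -4   4   0  -3   1   2  -2  -4  -3   2  -4  -2  -3   3  -1   1  -4
   11 D   4   0  -2   0  -4   2   3   3  -3  -4   1  -1   0  -3   1   4   1   2   4  -3
   12 N   0  -2  -1   4   2  -1  -3   0  -4   4   0   1   1  -3   4  -4  -4   4  -3   3
   13 D   2  -2   0  -3   2  -3  -3   0  -2   1  -4  -1   4  -1   1   3   0  -3   4   0
   14 E  -4   3  -1   4  -1  -4   4  -3  -3  -4  -1   3   3  -4   1  -4  -4   2   0  -4
   15 T   3   0  -3  -1   4   0  -2  -2   1   0   2   2   2   1   1   3  -4   0   4   2
   16 T   0   2   2   3   0   1  -1   2   1   3   0   3  -1   4   4   3   4  -3  -1   2
   17 P  -3  -4  -4  -3  -2  -1  -2   1   1   4  -4  -3   2   3   2   4   0   2  -3   2
   18 K  -2  -3   0   2   0   0  -2  -3   1  -1  -3   1   4  -3  -3   2   4   3   2   4
   19 R   2   1   2  -2  -3  -4  -3   0  -1  -1  -2  -2   3   3   4   1   4   3   1   1
   20 S  -3   3   3  -4   3   1  -4   4  -3  -3   3  -4  -1   1   4  -1   0   0   3  -4
   21 A  -2   2  -3   0  -3  -3   4   2   4  -4   0  -3   0  -1   0   1   4   4  -2   1
   22 L   1  -4   1  -2   1   3   4   4   0   4  -2   2  -3  -4   4  -4   2  -1  -2  -3
   23 T   4  -1   3   2  -4  -2  -4   1  -3   0   1  -3   3   4   3   3   0   4  -4   4
   24 A  -3   4  -1  -4   3   1   1  -2  -3   1  -1   0  -3   1   3  -1   1   1   1   0
   25 N  -2   0   3   1   2   0   0  -1  -2  -4   4   4   1   0  -3  -4   2   1  -1   0
   26 R  -1  -2   2   0   3   0   4  -4   1   4   1   1  -2  -1  -4  -4  -4  -3   4   2
   27 F   4   4  -1  -3   0  -1  -3  -3   4   1   2  -4   3  -2   4   1   0   4   0  -3
   28 F  -2  -1   2  -3  -4   4  -2   1  -1  -2  -2  -1   2  -4  -4   1  -2   0   0  -2
   29 R   3   3   3   2   1  -4   0  -1   0   4  -1   3   4   4   3  -3   1  -2  -1   4
   30 S   1   4   3  -4   3  -4  -4   3   1  -2   3   2  -4  -2   1   1   4   3   4   3
   31 D  -4   3  -1   3  -1   0   0   0  -2  -1   2  -3   0   3   4   4   1  -3   0  -1
   32 S   2  -4  -2   2  -1   0   1   4   1   3  -2   4   4   3  -3  -1   0   3   1  -3
   33 L   1   3   4  -3   4   4   2  -3   2   3   4   4   4   1  -4   0  -4   4   0  -1
   34 Q   1   1   2  -3  -1   0  -4  -4  -4  -2   3   4   3   2   4   0   1   2   1   3
   35 Y   1  -4   4  -2  -3   3   2  -3   1  -3   4  -1   0   2  -1   4   3  -1  -4  -2
   36 D  -1  -2  -4   0  -4  -1   1   2   2  -2   2  -2   1   2   1  -4  -3   0   3  -1
   37 C  -1   0   0  -1  -3  -3  -2   3  -1   4   2  -2   2   0   4   3  -1  -3  -1  -2
   38 F   3   4  -4  -2   1  -2   3   2  -4  -2   3  -4   4  -4  -3   1  -1  -4   4   4
   39 L  -3   3  -1  -3   3  -3  -3   1  -2   1   2  -3   0   3   2  -4   3   2   2   3
   40 A  -2   4   2   1  -4  -2   2   2   0   1   0   4  -4   3   0  -3  -4   0  -1   4
   41 D  -2  -1   4  -4   3   2   3  -2   3  -1   2   3   1  -3   4   3  -2   3  -4   1
   42 A   3   2  -3  -4   4   1   1   1  -1   0  -2  -1   1   0   3  -4   0   0  -3   2
   43 H  -1   3  -3  -4  -1  -2  -2  -2   2  -1  -4   3  -4  -3  -4  -3   2   1  -3   3
   44 C   1   1  -4  -1   1  -2   3   1   0  -2  -1   1  -2  -3   3  -3   1   3  -2   3
   45 F  -3   1   0   2  -1  -2  -3  -4   1   0   2   4   4  -1  -3   3   0  -1   4   1
   46 F  -2   2   2  -2   0  -1   3  -1  -3   1   4  -1   2   2   2  -4  -3  -1  -1   1
   47 G   0   4   3   2  -3   3   0  -1   2  -3  -3   4  -2   4   1  -4  -1   1  -4  -1
   48 K   2   4  -1   0   3   0   4  -4   0   3  -4   3  -2   0  -3   4  -3   4   0  -3
   49 I   0   1  -3  -2  -1   1   2   0   2   1  -2  -4   0   0  -2   1   0  -2  -1  -2
   50 V   2  -1  -2   2   4   3   2   3   0  -2  -2   0  -2   3   3  -3  -3  -1  -4   0
   51 F   0  -4  -1   1   4  -3  -1   2  -3  -4   2  -3   3   4   1  -1  -1   0   2   2
   52 L   1   0   2   4  -4   4   2  -4  -3   0   2  -3   2   4  -4   0  -3   1   4   0
   53 A  -3  -3   2   2  -4  -1  -1   4   4  -3   3   4   0   2  -2  -3   4   3   4   0
   54 C  -3  -2   4  -1   4  -1  -4   1   0  -4   2  -3  -3  -4  -3  -1   0  -2   0  -4
   55 G   1  -2   4   2   1  -1  -1  -3   0  -4   1   3   0  -3  -2  -2  -1  -2   4   3
   56 L   2   2   1   0   1   3   1  -3   2   0  -4  -4   4  -2   1  -2  -4  -2   0   1
   57 V  -2  -3  -1  -1  -3   3  -3  -2  -1  -4   0  -2   2  -4  -2  -4   2  -2   3   0
   58 R   0   1   0   2   1   0  -3   4   1  -1   1   2   3  -1  -3   2  -2  -3   3   1
   59 D   3  -3   1  -2   3   0  -3   4  -3  -2  -4  -1   4  -4  -2   3   0   0   1  -2
   60 Y  -3   2  -1  -4   2   1  -1   0  -3   2   3  -4   1   1   3   0   1   4  -3  -4
   61 Q   1   0   3  -3   0   4   3   4  -2   1   4  -3   1   0  -1   2   0   2   4   2
   62 L   4   4  -2   2  -2   4  -2  -2  -4  -3  -1   0   2   1  -1   3  -2  -1   3   2
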