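
Last position-specific scoring matrix computed
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 E  -1   0   2   3   2  -4  -2   3   3   2   0   2   4   0   4  -3   2   2   0  -1
    2 K  -2  -3   1   0   2   4  -3   1  -3   1   1   1   4   3  -1  -4   1   0  -1  -1
    3 I  -4  -2  -1   2   3   0   4  -1   0   1  -2  -2   0  -1   3  -2   2  -1   3  -2
    4 A   3   2  -4  -1  -4   3   0   0   4  -3  -4  -1  -4  -4   0   3   0   2  -2  -2
    5 D  -1  -3   1  -1   4   1   4   0   4   3  -3   1   3   1  -1   1  -1   1  -1  -2
    6 W   1  -3  -1  -1   4   0   4   4  -2   1   4  -4  -4  -4  -1   1   3   4  -1  -1
    7 M  -1   3  -2   4  -2  -2  -1   3  -3  -2   0  -4  -2  -3   2   0   1  -4  -3   0
    8 L  -1  -3   4  -3   3   0   4  -4   0  -4   3   4   4  -1   3  -1   3  -3  -4   2
    9 H  -3   4   0   0  -2  -3   0   1  -4   3  -2  -3   2  -3   1  -2  -4  -4  -2   3
   10 F  -2  -2  -1  -2  -4   4   0   2   1  -1  -3  -1   2  -3   1   3  -2   3   1   4
   11 I   4   1  -4  -4   2  -4   2   0   0  -3   2   3   0   4  -3   0  -4  -1   1  -3
   12 L  -3  -1  -2   2   4   4   0   0   2   0  -4   1   2   4  -2  -3   4   1   1   4
   13 L  -2   0   1   1   0  -1  -1  -2   0  -3  -1  -4  -3  -3   2   3  -3  -4  -1  -1
   14 D   4   0   4  -1   4   2  -3   4   2  -1   3   4  -2  -2   1   2   0   2   0  -1
   15 K  -4   1   4   2  -1   0   0   1  -4  -2   3   3   1   1   3   4  -4   2   1  -1
   16 K   1   2  -3   1   2   3  -3   2   1   0   4   3  -1   0  -3  -2   3   0   2  -4
   17 D   2   1   0   1   4   0   1  -2   1  -4   3   0  -2  -2  -3  -2  -2  -2  -2  -1
   18 S   2  -4   2   1   3  -3  -3   4  -3   1  -3  -2  -1   1  -4   3  -3   3  -2   4
   19 D  -2  -4  -1  -3   2   2   1   4  -3   2  -1   1  -4   0   2  -4  -2   3   0   1
   20 K   4   1  -2   2  -2   3   3   1   4   1  -1  -3   4   3   2   4   2   0  -3   2
   21 Q   3  -1   4   4   2  -1  -1  -3   0   1  -4  -2   3   1   1   4   3   4   1   0
   22 Q   3  -2   2   1   4   1  -1  -2  -4   0  -4  -3   0   2  -2  -2  -4   4   0  -2
   23 V   4   2  -1  -1   1   2  -2  -2   0   0  -4   0   3   3  -2   4   0  -1   2   4
   24 W   3  -4  -2   4  -4  -4   4   2  -2   2   0   3   1  -3  -2   1   2  -4   2   4
   25 F  -4  -1   2   1   4   0   1  -2  -3   1   1  -4   4  -1   0  -4   3   4   3   0
   26 K  -3  -4   0   0  -2   3   4  -3  -3   4  -4   3   3   1   4   1   2   4  -4  -1
   27 P   4  -1  -4  -4  -4   0  -3   0  -4  -4   2   0   1   4   2  -4  -4   2  -4   3
   28 D   0   4   2  -3   1  -3   2  -3  -3   0  -1   2  -2  -1   3   0  -2   0   4  -4
   29 V  -4  -4   1  -1   2   3   1   1  -4   3   0  -1   0   2   4   1   4   2  -2   1
   30 K  -3  -3  -1   2   2   4   3   1   3   1  -2   4  -2   4  -2   1   0   3  -3  -2
   31 A  -2   2   2   1   3   3  -2   0   2   4  -3   2  -4   2   1  -3  -4   2  -1  -3
   32 E  -2   2   4  -1   2   4   2   1  -1  -3  -2   2   2  -1   0   1  -3   3  -2  -2
   33 D   3  -2   2  -1   0   3  -2   4   2   4   0   3  -4   2   0  -3  -2  -3   3   0
   34 G   0  -1   2  -3  -1   1   4  -1   0  -2  -3  -4  -3  -2  -4   2   2  -1   2   1
   35 Y   2   2   0   4   1  -3  -1  -1  -2   3   0   2  -4   2  -1   1   3  -2  -2   3
   36 V   0   2   0  -3   1  -1  -3   0   4   3  -1   4   2   4  -4  -1  -2   2  -1   4
   37 E   1   1   3   1  -1   3   3   3  -1  -3   2  -4  -4  -1  -2  -2  -3  -2   0  -4
   38 Q   0   3  -2  -3  -1   1   1   1   1   3  -4   1   2  -2  -1   2   1   3  -3   4
   39 V   0  -2   2  -4   0  -3   2   2  -1   2  -1   3   4   1   4  -4  -4  -1   0  -4
   40 Q   3   0  -2   4  -1   0   2  -1  -1  -1  -4  -3  -2   0  -1  -4  -4   0   2   3
   41 T  -2  -4   1   1   1   0   4  -2  -1   0   0  -2  -3  -2   0  -1   3   2  -1  -3
   42 G   2  -1   2   2  -1  -4   0  -1   1   2   0   2  -1  -2   2  -4   1   3   0   3
   43 D   4   2  -1  -4   3   3  -2   3   4   2   0   1  -2   2  -1   1   1  -1   4   1
   44 D  -3  -2   3  -2  -2   2  -4   3   2   3  -2   2   4   3  -1  -1   2   0   1   4
   45 S  -4  -2  -4   1   0  -1   1   1  -1   3   4  -1  -2   2  -1  -2  -3  -4   2  -4
   46 A   0  -4   2   2   2  -2  -1  -3  -4  -3   3  -4   3   3  -3  -4   1   0   0   0
   47 V  -2   0   3   3  -2  -3   2  -2   3  -2   3   4   1  -4  -4   4  -2   0   1  -4
   48 Q   4   3  -1   4   0  -4   0   4   4   0   3   0   2  -2   0   1   3   2  -3  -1
   49 H  -3  -4  -2   1   4  -4  -4  -1  -1   3   0  -2  -1  -2   0   0   2  -4   0  -4
   50 V   4  -1  -4   0   4   3  -4  -2   3  -4  -2  -4   3   1   3   4  -2   1  -1   2
   51 Q   3   0   3  -1   2  -2  -2   1   1   4  -2  -1  -4  -1   2   0   0  -3   0  -1
   52 F   1   4   0   4   2  -2  -2  -1   0  -3   0  -1   0   3   3   4  -4   4  -3  -4
   53 T   1   2   2  -1  -3   1   4   2  -2   0  -1  -4  -1  -4  -1   3   2   0   4  -1
   54 Q   2   3   1   1  -3   2   0  -3   4   4  -3   4   2   0   0  -2  -2  -1  -3  -2
   55 K   4  -2   0   0  -4   4   4   4  -1   1   4   1   4   4  -4  -4   2   1   3  -2
   56 R  -1   3  -1   4   2  -3   0  -4   4   1   2  -2   2   3  -2   2   0   4  -1   0
   57 F   1  -2   3  -3   3  -3   1  -1   3  -4   0   0   3  -2   3   2  -3   2   3   2
   58 T   2  -3   4   0  -4   1   0   0   3   0   0  -2   0  -4  -3  -3  -4  -4   4  -3
   59 L   1  -4   4   2  -2   4   4   0  -1   0  -4   0   4   3  -1  -4   1   1   3   0
   60 W   4   2  -1  -1  -4  -4   4   3  -1   0   3  -1  -3   3  -1  -4  -2   4  -3  -1
   61 C   4   2  -4  -1  -3   4  -2   2   0   3   2  -3   3  -1  -3   1   1  -2   3   2
   62 D  -1   0  -3   4  -4   2  -1   4  -4  -3   3  -3   3   0   2   0   0   3   0   1
   63 G  -3   4   0   3   3  -1   4   0   2   3   3   4  -2  -4   3  -2   1  -4   1   0
   64 W   0   2  -3   0   4   2  -3  -2   1   0  -1   3  -2   2  -4  -3  -4   2   1   1
   65 C   2   2  -3   1  -2  -4   3  -2   2  -1  -2   0   4   1   1   3  -1   3   1   1
   66 K  -4  -2  -4  -1  -1   2  -3   0   2   0  -3  -1  -4   0   4  -1   2  -1   2   2
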