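
Last position-specific scoring matrix computed
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 F   0  -2  -2   4  -4  -1  -1   3   0   1   4  -1   2  -1   3  -2  -3   2  -3   1
    2 S   3  -1  -2   4  -3  -1  -3  -3  -2  -2   2   3   3   0   3  -2   2   1  -4  -4
    3 V  -2   0   4   2   2  -2   1   2   4   3  -3   0   4  -4   2  -4   2   2   4   2
    4 Y  -2  -4  -2   2   0   0  -1  -1  -3  -3  -1  -1  -4  -3   2  -1  -1  -1  -4  -3
    5 H  -2  -3   0   4  -4   1   0   0  -3   2   4   0   2   2   3  -2   4  -2   3  -3
    6 G  -2   1  -4   0  -1  -2   1  -3  -3   0  -2  -3   1   1  -4   0  -1   0  -3   3
    7 K   2  -2   4  -2   2   3   2  -4  -1   0  -2   4  -2  -3  -4   4  -1   3  -2  -3
    8 T   0  -1   2   2   4  -3  -2   0   4  -3   3   3  -3  -3  -2  -1   4  -4   1   2
    9 Y  -3  -4  -1   2   4   3   3  -1  -4  -1   1   2   4  -3  -4  -2   3   0   4  -2
   10 C  -4   2  -4   0   2   0  -2   0  -2   2  -2   4  -1   4  -4   3  -1   0   0  -2
   11 C   0  -4   0   4   4  -2   0   3  -1   4  -1   1   0   1  -1  -4  -3  -3   0   4
   12 S   2   1  -2  -1  -2  -2  -4  -3  -1   0   1  -3  -3   0   1   1  -2   1  -4  -1
   13 H  -4   2   1  -1   4  -2   3  -3   3  -2   2   3   0  -3   2   1  -3   2   2  -3
   14 F   1  -3  -3  -4   1   2   2   1  -2   2  -3   1   4   4  -2   1  -3   3   3  -1
   15 Y   2   4  -4   4  -4   4   2   1   1   4   4  -1  -1   3  -3   1  -3   0   1  -2
   16 K   0   4   0  -3   0  -1   2   1  -3  -2  -4   3  -1  -2   3   4  -4   0   0   0
   17 F  -1  -2   0   3   4  -4   2  -2   3  -2   2   3   3  -3   3   4   4  -3  -1   4
   18 Y   2  -3  -4   3   1  -4  -2  -1  -1  -3   3   0  -3  -2   3   1  -2   3  -4   3
   19 Q   0  -4  -1  -1  -2   2  -4   3   4  -2  -1   1   0   0   3   1  -4  -1   4   4
   20 W   2   4  -4   4   1  -2  -4   1  -2   1  -3  -1  -1   1   0  -1  -4  -1   3  -1
   21 Q   1  -4   1  -2   1  -3   0  -1  -2  -2   4  -2   1  -3  -4  -3  -4   2   3  -3
   22 C   2   4  -3  -4   4   1   3  -1   1   0   1   1   4   4  -4   1  -2   1  -2   2
   23 W  -1  -1   1  -2  -1  -3   3   0  -1   3  -2  -3   2  -2   0   4  -4  -2   4  -3
   24 F  -2  -4   2   1  -4  -4  -2   0  -4   1  -2  -2  -4  -2  -2   0   2   3   4   2
   25 C   1   4  -1   3  -2  -3  -1   1   4  -3   0   3   1  -1  -2   1   2  -4   3  -2
   26 R  -2  -2   3   3  -3   4   4  -4   2   0   3   2  -3  -3  -2  -3   1  -3  -2   3
   27 T   2  -1   0   2   1   3   1   2  -1  -2   2   0  -1  -3   1   0   1   4  -2   2
   28 F   2   4  -1   4  -3   1  -2  -3   1   4   4  -1   1  -4   1  -2   3   4   0   2
   29 A   3  -3   4   4  -1  -2  -2   1  -3   2  -2   2   1  -4   2   3   3   1   0  -2
   30 L  -4  -3   0  -2   0  -3   1  -3   1   1   1  -1  -1   0  -3  -1   3   3   1  -2
   31 K  -1  -3   0   0  -1   3   1   2   1   2  -2  -4   1  -1   3  -1   0  -1   2  -3
   32 N   2   1   1  -4  -1  -3   0  -3   3   3   4  -4   4  -4  -4   3  -3   0   1  -1
   33 V  -2   2   0   1   4  -2  -1  -1  -1   2   0  -2   0  -2   3   1  -2  -2  -2   4
   34 W  -3   4   3  -2   3   3   2  -3  -1   0  -3   0   1  -1   2   4  -3   3  -3   3
   35 F  -2  -2   1  -4  -4   1   1   4  -4  -4  -1   2   4   2  -2   1  -2  -2  -4  -3
   36 W  -2   2   1  -4   1  -4   1   2   2   2   3   1   4   4   0   3   0   0  -4  -4
   37 C   1   4  -3  -1   2   0   3  -4   0  -3  -3  -1   0  -2   4  -3   4   0  -3  -2
   38 Y  -3   0   3  -2   2  -3  -4   2   4   1   4  -3  -3   4  -4   3   4   2   3  -2
   39 G  -4  -2  -4   2  -2   2   3   3   2  -3  -2  -4  -4  -1   1   1   2   1  -4   0
   40 W  -4   3   4   4  -4  -3   3  -2   0  -3   2   3   4   3   4   2  -4  -4   2  -3
   41 M  -1  -2  -1  -1   3   0   1  -4  -2   0   0  -2   3   2   0   4   3  -4  -3   0
   42 C   0   3   2   2   4   3  -3   3   2   1   0   2   4   1   4  -1  -1  -4   0   1
   43 A   3   0  -4   2   1   0  -3   1   2  -3   1  -3  -4   0  -3   0  -3  -1  -1   0
   44 C  -2  -2  -3   0  -4   4   3  -4   1   1   1   0   1  -2   0   4  -4   1  -2  -1
   45 P   1   1  -1  -4  -2   0   4   3   3   3   2   4   1   2   2  -4   1   0   2   2
   46 N   3   0  -2   0   1  -1   4   3   4   4   1   1   1   1   3  -2  -3  -2   3   2
   47 V   1  -2  -4   2  -3  -4   4  -3   4  -3  -4   1  -4   0  -3  -4  -4  -1  -1  -4
   48 N   4   0   0  -3   4   4   2  -4   1  -3   2   0  -4   4  -1   3   2  -3   1   1
   49 V   3   0  -3   3   2  -2   2  -2  -4   3   4   4   3  -1  -3   3   4  -3   4   4
   50 I   0  -4   4  -2   4   3  -2  -2  -3   3  -3   0   0  -1   0  -3   3   4   2   2
   51 A   0   0   2  -2   0  -3   4  -4  -1  -3  -3   4   4  -2   1   0   3   1  -4  -3
   52 H  -4  -4  -2  -4  -4  -2   4   0   4   4   2   4  -1  -3   1  -4  -1  -2   0   1
   53 I   3   1  -1  -3  -1   2  -2   0   3  -1   1  -1  -1  -1   3  -4   4  -2  -4  -1
   54 G  -2  -2  -3  -2   1  -2   4   0  -2   4  -2   0   1  -4   2   4   4   2  -3   4
   55 C  -4  -4  -1  -1  -4  -2  -1  -3  -2  -2  -4   3  -3   4   4   1  -1  -2  -1  -1
   56 L   1   1  -4   0  -3   1   0   3   4   3   0   2   4   3   1   3  -4   2   4   4
   57 I   3   3  -2   0  -1   3   1   3   2   1   0   1  -1  -4   4   3   3   2   1  -2
   58 S  -4  -2  -4   1   4   1  -3  -2  -2   2   2   2   3   4   0   1  -4   2   2  -2
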