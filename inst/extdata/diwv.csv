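res,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
A,1.0,1.0,1.0,-7.49,44.94,1.0,1.0,1.0,-7.49,1.0,1.0,1.0,1.0,1.0,20.26,1.0,1.0,1.0,1.0,1.0
R,1.0,58.28,13.34,1.0,1.0,20.26,1.0,-7.49,20.26,1.0,1.0,1.0,1.0,1.0,20.26,44.94,1.0,58.28,-6.54,1.0
N,1.0,1.0,1.0,1.0,-1.88,-6.54,1.0,-14.03,1.0,44.94,1.0,24.68,1.0,-14.03,-1.88,1.0,-7.49,-9.37,1.0,1.0
D,1.0,-6.54,1.0,1.0,1.0,1.0,1.0,1.0,1.0,1.0,1.0,-7.49,1.0,-6.54,1.0,20.26,-14.03,1.0,1.0,1.0
C,1.0,1.0,1.0,20.26,1.0,-6.54,1.0,1.0,33.6,1.0,20.26,1.0,33.6,1.0,20.26,1.0,33.6,24.68,1.0,-6.54
Q,1.0,1.0,1.0,20.26,-6.54,20.26,20.26,1.0,1.0,1.0,1.0,1.0,1.0,-6.54,20.26,44.94,1.0,1.0,-6.54,-6.54
E,1.0,1.0,1.0,20.26,44.94,20.26,33.6,1.0,-6.54,20.26,1.0,1.0,1.0,1.0,20.26,20.26,1.0,-14.03,1.0,1.0
G,-7.49,1.0,-7.49,1.0,1.0,1.0,-6.54,13.34,1.0,-7.49,1.0,-7.49,1.0,1.0,1.0,1.0,-7.49,13.34,-7.49,1.0
H,1.0,1.0,24.68,1.0,1.0,1.0,1.0,-9.37,1.0,44.94,1.0,24.68,1.0,-9.37,-1.88,1.0,-6.54,-1.88,44.94,1.0
I,1.0,1.0,1.0,1.0,1.0,1.0,44.94,1.0,13.34,1.0,20.26,-7.49,1.0,1.0,-1.88,1.0,1.0,1.0,1.0,-7.49
L,1.0,20.26,1.0,1.0,1.0,33.6,1.0,1.0,1.0,1.0,1.0,-7.49,1.0,1.0,20.26,1.0,1.0,24.68,1.0,1.0
K,1.0,33.6,1.0,1.0,1.0,24.64,1.0,-7.49,1.0,-7.49,-7.49,1.0,33.6,1.0,-6.54,1.0,1.0,1.0,1.0,-7.49
M,13.34,-6.54,1.0,1.0,1.0,-6.54,1.0,1.0,58.28,1.0,1.0,1.0,-1.88,1.0,44.94,44.94,-1.88,1.0,24.68,1.0
F,1.0,1.0,1.0,13.34,1.0,1.0,1.0,1.0,1.0,1.0,1.0,-14.03,1.0,1.0,20.26,1.0,1.0,1.0,33.601,1.0
P,20.26,-6.54,1.0,-6.54,-6.54,20.26,18.38,1.0,1.0,1.0,1.0,1.0,-6.54,20.26,20.26,20.26,1.0,-1.88,1.0,20.26
S,1.0,20.26,1.0,1.0,33.6,20.26,20.26,1.0,1.0,1.0,1.0,1.0,1.0,1.0,44.94,20.26,1.0,1.0,1.0,1.0
T,1.0,1.0,-14.03,1.0,1.0,-6.54,20.26,-7.49,1.0,1.0,1.0,1.0,1.0,13.34,1.0,1.0,1.0,-14.03,1.0,1.0
W,-14.03,1.0,13.34,1.0,1.0,1.0,1.0,-9.37,24.68,1.0,13.34,1.0,24.68,1.0,1.0,1.0,-14.03,1.0,1.0,-7.49
Y,24.68,-15.91,1.0,24.68,1.0,1.0,-6.54,-7.49,13.34,1.0,1.0,1.0,44.94,1.0,13.34,1.0,-7.49,-9.37,13.34,1.0
V,1.0,1.0,1.0,-14.03,1.0,1.0,1.0,-7.49,1.0,1.0,1.0,-1.88,1.0,1.0,20.26,1.0,-7.49,1.0,-6.54,1.0
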