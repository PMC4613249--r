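>pos_1
TCDGAVMTKTNSTGKINPISSVNTWPGSYSPHCPQKVVNPPSGVAIGSTVN
>pos_2
SVQPNIEGNNPTPVQGNSPNTNASGAWNTKLCPSGTGAWLNPNANMTSNISPIS
>pos_3
VCMTANDSITGSLIDFVSSVIPGSSLHQTVPFANLQQVRTIVTSATSIMTIISPLQHGVIQP
>neg_1
EKIADWMLHFILLDKKDSDKQQVWFKPDVKAEDGYVEQVQTGDDSAVQHVQFTQKRFTLWCDGWCK
>neg_2
CESDEGHINDDNDETTPKRSALTANRFFRSDSLQYDCFLADAHCFFGKIVFLACGLVRDYQL
>neg_3
FSVYHGKTYCCSHFYKFYQWQCWFCRTFALKNVWFWCYGWMCACPNVNVIAHIGCLIS
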