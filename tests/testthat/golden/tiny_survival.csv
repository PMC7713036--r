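arm,t,h,S,risk,area
short_term,1,0,1,0,6.7950937950938
short_term,2,0,1,0,6.7950937950938
short_term,3,0,1,0,6.7950937950938
short_term,4,0.0909090909090909,0.909090909090909,0.0909090909090909,6.7950937950938
short_term,5,0.111111111111111,0.808080808080808,0.191919191919192,6.7950937950938
short_term,6,0.142857142857143,0.692640692640693,0.307359307359307,6.7950937950938
short_term,7,0,0.692640692640693,0.307359307359307,6.7950937950938
short_term,8,0,0.692640692640693,0.307359307359307,6.7950937950938
longer_term,1,0,1,0,7.25
longer_term,2,0,1,0,7.25
longer_term,3,0,1,0,7.25
longer_term,4,0,1,0,7.25
longer_term,5,0,1,0,7.25
longer_term,6,0.25,0.75,0.25,7.25
longer_term,7,0,0.75,0.25,7.25
longer_term,8,0,0.75,0.25,7.25
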