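# Published 50-bird graded-scheme prevalence table (mean +/- SE % of 50
# assessed birds per flock): feather-loss head/back at minor (<5 cm, score 1)
# and major (>5 cm, score 2) severity, and minor dirtiness.  p and se in
# percent; k = p*50/100 birds.
house_id,indicator,score_level,p,se
1,fl_head,1,24,6.1
1,fl_head,2,28,6.4
1,fl_back,1,26,6.3
1,fl_back,2,28,6.4
1,dirtiness,1,6,3.4
2,fl_head,1,6,3.4
2,fl_head,2,0,0
2,fl_back,1,12,4.6
2,fl_back,2,2,2
2,dirtiness,1,30,6.5
3,fl_head,1,16,5.2
3,fl_head,2,0,0
3,fl_back,1,26,6.3
3,fl_back,2,32,6.6
3,dirtiness,1,0,0
4,fl_head,1,0,0
4,fl_head,2,0,0
4,fl_back,1,2,2
4,fl_back,2,0,0
4,dirtiness,1,4,2.8
5,fl_head,1,18,5.5
5,fl_head,2,0,0
5,fl_back,1,10,4.3
5,fl_back,2,6,3.4
5,dirtiness,1,30,6.5
6,fl_head,1,8,3.9
6,fl_head,2,0,0
6,fl_back,1,6,3.4
6,fl_back,2,0,0
6,dirtiness,1,16,5.2
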